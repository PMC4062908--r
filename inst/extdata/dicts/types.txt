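# study-design type words/phrases
cross-sectional
case-control
case control
observational
longitudinal
prospective
retrospective
randomized controlled
population-based
qualitative
descriptive
epidemiological
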