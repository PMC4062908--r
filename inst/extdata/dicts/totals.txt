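# population-total container nouns
cohort
cohorts
sample
samples
population
populations
group
groups
total
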