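associated
related
correlated
linked
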