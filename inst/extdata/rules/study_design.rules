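# study-type cue adjacent to a design-type word
[@st a(types)]
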