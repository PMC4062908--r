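a(relations) eq('between') [@multiple] eq('and') @multiple
[@multiple] a(be) a(related) a(with) eq('onset')? eq('of')?
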