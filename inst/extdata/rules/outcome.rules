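@factors eq('of') [@multiple]
@multiple a(be) a(adverbs) a(related) a(with) [@multiple]
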