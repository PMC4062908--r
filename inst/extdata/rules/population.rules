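a(totals) re('(of|on|in)') [@stats a(clusters)]
@multiple re('with|in|on')? [a(clusters) re('with|without') @multiple]
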