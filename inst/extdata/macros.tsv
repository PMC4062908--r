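# macro name<TAB>mini-pattern in the rule notation (BUILTIN = hard-coded)
st	a(study-cues)
stats	a(STATS_NUMBER)
perce	a(PERCENT)
factors	a(factors)
synonyms	a(synonyms)
or	eq('(')? re('or|rr|hr|aor') eq('=') a(STATS_NUMBER) eq(',')?
ci	a(PERCENT) eq('ci') eq(':') a(STATS_NUMBER) eq(',') a(STATS_NUMBER) eq(')')?
multiple	BUILTIN
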