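# population cluster (people) nouns
men
women
children
adults
adolescents
patients
participants
subjects
individuals
infants
veterans
elderly
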