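# surface<TAB>kind; human-population cues take precedence over non-human hits
human	human
humans	human
patient	human
patients	human
men	human
women	human
children	human
adults	human
adolescents	human
infants	human
participants	human
subjects	human
volunteers	human
mice	non_human
mouse	non_human
murine	non_human
rat	non_human
rats	non_human
zebrafish	non_human
drosophila	non_human
dog	non_human
dogs	non_human
canine	non_human
pig	non_human
pigs	non_human
porcine	non_human
rabbit	non_human
rabbits	non_human
monkey	non_human
monkeys	non_human
macaque	non_human
bovine	non_human
sheep	non_human
yeast	non_human
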