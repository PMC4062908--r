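# term<TAB>semantic group (15 coarse groups; unmapped mentions fall back to "Other")
obesity	Disorders
overweight	Disorders
abdominal obesity	Disorders
childhood obesity	Disorders
central obesity	Disorders
hypertension	Disorders
type 2 diabetes	Disorders
diabetes mellitus	Disorders
t2dm	Disorders
dyslipidemia	Disorders
hypercholesterolemia	Disorders
metabolic syndrome	Disorders
cardiovascular disease	Disorders
coronary heart disease	Disorders
coronary artery disease	Disorders
atherosclerosis	Disorders
stroke	Disorders
cancer	Disorders
asthma	Disorders
depression	Disorders
inflammation	Disorders
insulin resistance	Disorders
hernia	Disorders
body mass index	Physiology
body weight	Physiology
waist circumference	Physiology
waist to hip ratio	Physiology
blood pressure	Physiology
bone mineral density	Physiology
birth weight	Physiology
weight gain	Physiology
weight loss	Physiology
adiposity	Physiology
mortality	Physiology
morbidity	Physiology
age	Physiology
gender	Physiology
maternal age	Physiology
gestational age	Physiology
parity	Physiology
sleep duration	Physiology
short sleep duration	Physiology
physical activity	Activities/behaviors
physical inactivity	Activities/behaviors
exercise	Activities/behaviors
smoking	Activities/behaviors
smoking status	Activities/behaviors
alcohol consumption	Activities/behaviors
diet	Activities/behaviors
energy intake	Activities/behaviors
coffee intake	Activities/behaviors
education	Activities/behaviors
race	Concepts/ideas
ethnicity	Concepts/ideas
socioeconomic status	Concepts/ideas
social class	Concepts/ideas
marital status	Concepts/ideas
family history	Concepts/ideas
income	Concepts/ideas
occupation	Occupations
bariatric surgery	Procedures
leptin	Chemicals/drugs
visceral adipose tissue	Anatomy
subcutaneous adipose tissue	Anatomy
vat	Anatomy
sat	Anatomy
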