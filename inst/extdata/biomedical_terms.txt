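# Biomedical-term gazetteer feeding the MULTIPLE_TERM tag layer.
# Reconstructed stand-in for a UMLS/Specialist look-up layer: seeded from
# high-frequency concepts of the obesity epidemiological literature.
# Extendable with C-value term-recognition output.
obesity
overweight
abdominal obesity
childhood obesity
central obesity
body mass index
body weight
waist circumference
waist to hip ratio
blood pressure
bone mineral density
insulin resistance
metabolic syndrome
type 2 diabetes
diabetes mellitus
clinical history of diabetes mellitus
t2dm
hypertension
dyslipidemia
hypercholesterolemia
cardiovascular disease
coronary heart disease
coronary artery disease
atherosclerosis
stroke
cancer
asthma
depression
inflammation
hernia
mortality
morbidity
physical activity
physical inactivity
exercise
smoking
smoking status
alcohol consumption
diet
energy intake
coffee intake
sleep duration
short sleep duration
weight gain
weight loss
adiposity
birth weight
maternal age
gestational age
parity
age
gender
race
ethnicity
education
income
occupation
marital status
socioeconomic status
social class
family history
bariatric surgery
leptin
visceral adipose tissue
vat
subcutaneous adipose tissue
sat
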