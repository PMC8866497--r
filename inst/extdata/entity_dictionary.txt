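bladder
urothelial
carcinoma
obstruction
smoking
copd
diabetes
hypertension
anemia
fatigue
carotid
lesion
ambulatory
stable
review
benign
routine
hydration
appetite
mobility
history
followup
abnormal
consultation
service
movement
tumor
prostate
lung
nodule
mass
biopsy
metastasis
dyspnea
cough
pain
chest
fracture
stroke
infection
renal
hepatic
cardiac
arrhythmia
angina
asthma
pneumonia
edema
weight
anxiety
depression
insomnia
nausea
vomiting
diarrhea
constipation
hematuria
dysuria
incontinence
impotence
radiotherapy
chemotherapy
surgery
gleason
psa
stage
grade
squamous
adenocarcinoma
emphysema
fibrosis
effusion
atelectasis
bronchitis
osteoporosis
arthritis
dementia
delirium
seizure
neuropathy
retinopathy
cataract
glaucoma
obesity
malnutrition
dehydration
sepsis
thrombosis
embolism
aneurysm
stenosis
ischemia
infarction
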