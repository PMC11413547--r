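pain
painful
ache
aching
chronic
doctor
doctors
physician
nurse
hospital
clinic
surgery
medication
medications
meds
medicine
prescription
dose
dosage
treatment
treatments
therapy
physio
symptom
symptoms
diagnosis
diagnosed
condition
disease
illness
injury
nerve
nerves
spine
spinal
joint
joints
muscle
muscles
inflammation
arthritis
fibromyalgia
migraine
headache
backache
fatigue
insomnia
nausea
dizzy
numb
numbness
flare
flares
disability
disabled
health
healthcare
specialist
referral
mri
xray
scan
bloodwork
pharmacy
opioid
opioids
ibuprofen
acetaminophen
gabapentin
steroid
injection
injections
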