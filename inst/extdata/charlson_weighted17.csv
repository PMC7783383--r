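flag,condition,weight
myocardial_infarction,myocardial_infarction,1
congestive_heart_failure,congestive_heart_failure,1
peripheral_vascular_disease,peripheral_vascular_disease,1
cerebrovascular_disease,cerebrovascular_disease,1
dementia,dementia,1
chronic_pulmonary_disease,chronic_pulmonary_disease,1
rheumatic_disease,rheumatic_disease,1
peptic_ulcer_disease,peptic_ulcer_disease,1
mild_liver_disease,mild_liver_disease,1
diabetes,diabetes,1
diabetes_with_complications,diabetes_with_complications,2
hemiplegia,hemiplegia,2
renal_disease,renal_disease,2
malignancy,malignancy,2
moderate_severe_liver_disease,moderate_severe_liver_disease,3
metastatic_solid_tumour,metastatic_solid_tumour,6
aids_hiv,aids_hiv,6
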