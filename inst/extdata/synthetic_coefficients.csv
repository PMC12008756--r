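# center age_menarche 15
# center breastfeeding_months 0
# center height_cm 160
# prs_variance 0.098596
term,beta,freq
age_menarche,-0.04,
first_live_birth,-0.2,
additional_live_births,-0.05,
breastfeeding_months,-0.002,
benign_breast_disease,0.45,
family_history,0.47,
height_per_10cm,0.08,
bmi_under_18.5,0.05,
bmi_25_29.9,0.02,
bmi_30plus,-0.1,
alcohol,0.25,
prs,1,
pv_BRCA1,2.3,0.0015
pv_BRCA2,1.7,0.0015
pv_PALB2,1.6,8e-04
pv_ATM,0.7,0.001
pv_CHEK2,0.9,0.001
pv_BARD1,0.7,5e-04
pv_RAD51C,0.7,3e-04
pv_RAD51D,0.7,3e-04
pv_TP53,1.9,2e-04
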