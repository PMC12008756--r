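id,status,age,age_menarche,parity,breastfeeding_months,benign_breast_disease,family_history,height_cm,bmi,alcohol,prs,pv_BRCA1,pv_BRCA2,pv_PALB2,pv_ATM,pv_CHEK2,pv_BARD1,pv_RAD51C,pv_RAD51D,pv_TP53
ctrl_1,0,60.5,16,9,60.8,0,0,162,32.5,0,0.246684,,,,,,,,,
ctrl_2,0,62.6,16,4,98.5,0,0,152.7,21.6,0,0.068628,,,,,,,,,
ctrl_3,0,34.9,,7,1,0,0,154.8,23.1,0,0.420063,0,0,0,0,0,0,0,0,0
ctrl_4,0,55,17,10,123.5,1,0,159.2,32,0,-0.046185,0,0,0,0,0,0,0,0,0
ctrl_5,0,47,19,0,1.9,0,0,162,29.5,0,-0.24764,,,,,,,,,
ctrl_6,0,42.8,14,3,37.5,0,0,173,22.6,0,0.317905,0,0,0,0,0,0,0,0,0
ctrl_7,0,50.6,15,4,142.1,0,0,163.7,17.1,0,-0.072777,0,0,0,0,0,0,0,0,0
ctrl_8,0,28.5,,6,88.5,0,0,160.1,20.5,0,0.635448,,,,,,,,,
case_1,1,35.1,17,5,103.6,0,0,158.5,23.4,0,0.267422,,,,,,,,,
case_2,1,38.7,16,7,60,0,0,168.7,15.2,0,0.132242,,,,,,,,,
case_3,1,56.8,17,1,97.6,0,0,158.3,42.3,0,0.073466,,,,,,,,,
case_4,1,46.8,17,2,53.3,0,0,155.5,31.4,0,-0.373823,,,,,,,,,
case_5,1,46.8,18,1,25,0,0,149.9,18.7,0,-0.120245,,,,,,,,,
case_6,1,48.9,17,1,53.2,0,0,157,33,0,0.324907,0,0,0,0,0,0,0,0,0
case_7,1,47.3,14,4,128.7,0,0,159.2,,0,0.447936,0,0,0,0,0,0,0,0,0
case_8,1,36.3,14,5,57.1,0,0,154.7,25.2,0,0.111758,,,,,,,,,
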