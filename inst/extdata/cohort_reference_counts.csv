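site,n_patients,age_median,age_min,age_max,female,male,breast,bowel,dlbcl,lung,ovarian,creatinine_changes,bilirubin_changes,temporal_shift
hospital_1a,627,55,18,88,440,187,249,216,162,0,0,36,59,1
hospital_2,144,62,18,84,78,66,19,98,27,0,0,17,24,1
hospital_3,1280,60,18,86,725,525,426,744,110,0,0,215,184,1
hospital_1b,1563,64,18,90,1308,255,470,358,0,126,609,104,92,1.05
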