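tumour_type,regimen,drugs,n_drugs
breast,AC,doxorubicin;cyclophosphamide,2
breast,EC,epirubicin;cyclophosphamide,2
breast,TC,docetaxel;cyclophosphamide,2
bowel,capecitabine,capecitabine,1
bowel,CAPOX,capecitabine;oxaliplatin,2
bowel,FOLFOX,folinic acid;fluorouracil;oxaliplatin,3
bowel,FOLFIRINOX,folinic acid;fluorouracil;irinotecan;oxaliplatin,4
dlbcl,R-CHOP,rituximab;cyclophosphamide;doxorubicin;vincristine,4
dlbcl,R-CVP,rituximab;cyclophosphamide;vincristine,3
lung,carboplatin-pemetrexed,carboplatin;pemetrexed,2
lung,cisplatin-etoposide,cisplatin;etoposide,2
lung,docetaxel,docetaxel,1
ovarian,carboplatin,carboplatin,1
ovarian,carboplatin-paclitaxel,carboplatin;paclitaxel,2
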