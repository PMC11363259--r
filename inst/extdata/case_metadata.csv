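case_id,surgeon,indication,age_years,bmi_kg_m2,uterus_weight_g,duration_min,special_feature
1,A,"Adenomyosis, Fibroids",47,22.3,240,75,"Peritoneal endometriosis"
2,A,"Fibroids",44,21.8,368,72,""
3,A,"Fibroids",45,20.5,202,85,"Adhesions, ovarian cyst"
4,B,"Fibroids",45,38.5,375,103,"Laparoscopic morcellation"
5,B,"Fibroids",58,35.3,104,82,"Adnexectomy, adhesions"
6,B,"CIN III, Hypermenorrhea",49,21.0,130,65,"Vaginal morcellation, deep infiltrating endometriosis, adhesions"
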