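query,label,tp,fp,fn,tn
overall,image_type,2548,133,463,47
overall,surveillance,690,292,264,1763
overall,suspicious,247,755,84,1922
overall,recurrence,105,353,19,2531
per_type,bone_scan,23,0,0,2988
per_type,chest_xray,1039,0,281,1691
per_type,ct_chest,841,0,61,2109
per_type,ct_abdomen_pelvis,63,0,64,2884
per_type,ct_chest_abdomen_pelvis,116,0,7,2888
per_type,ct_head,131,0,18,2862
per_type,mri_body,28,0,30,2953
per_type,mri_brain,41,0,1,2969
per_type,pet,266,0,1,2744
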