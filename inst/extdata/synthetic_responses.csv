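"participant_id","age_months","sex","cohort","rm_mouthing","rm_02","rm_03","rm_04","rm_05","rm_06","rm_07","rm_08","rm_09","rr_arranging","rr_placement","rr_media","rr_04","rr_05","rr_06","rr_07","rr_08","rr_09","rr_10","rs_parts","rs_visual","rs_movement","rs_04","rs_05","rs_06","rs_07","rs_08","sd_01","sd_02","sd_03","sd_04","sd_05","sd_06","sd_07"
"P001",14.2,0,0,0,1,1,1,1,2,2,4,2,0,1,1,0,1,2,1,1,1,1,3,3,1,4,3,0,1,1,3,2,2,1,3,4,4
"P001",16.9,0,0,3,0,1,1,2,1,0,2,1,0,1,1,0,0,1,0,4,1,0,0,1,0,1,1,1,1,0,0,3,1,1,1,0,1
"P001",19.6,0,0,0,3,1,1,1,0,0,1,0,2,1,1,1,1,0,1,0,3,0,2,1,0,0,3,0,0,3,1,0,3,3,1,1,0
"P001",23.5,0,0,1,0,1,1,0,1,1,0,0,1,0,0,1,1,1,1,1,1,3,2,4,3,1,0,0,1,1,0,1,2,2,1,1,1
"P002",11.4,0,0,2,3,3,4,1,4,2,3,4,1,3,0,1,0,1,1,1,0,1,1,0,1,1,1,1,1,0,1,0,3,3,0,1,2
"P002",16.1,0,0,2,3,0,0,2,4,3,0,1,0,0,1,1,1,0,0,1,1,1,1,0,1,2,1,0,0,1,0,0,1,0,1,1,1
"P003",8.1,0,0,3,0,1,2,2,2,2,4,2,1,1,1,1,0,2,0,1,0,0,1,1,1,1,1,3,1,0,2,3,2,3,3,4,3
"P003",11.6,0,0,1,2,1,0,4,0,0,0,4,1,1,1,4,0,2,2,3,3,2,2,1,2,3,0,0,2,2,3,1,0,4,1,0,4
"P003",15.2,0,0,3,3,1,1,1,3,1,4,0,1,1,1,0,1,0,0,1,1,3,0,1,0,3,1,1,0,1,0,2,1,2,2,4,2
"P004",14.4,1,0,0,0,0,1,0,1,0,0,3,1,0,1,0,1,0,0,1,1,1,1,0,2,0,0,1,1,2,1,1,1,1,0,2,2
"P004",18,1,0,0,0,1,1,0,0,0,3,0,0,1,2,3,0,0,1,1,1,2,2,3,2,2,1,0,1,2,2,2,3,2,2,1,0
"P004",20.2,1,0,1,1,0,0,1,0,1,1,1,2,0,0,0,1,1,1,3,3,1,1,1,0,4,0,0,3,0,0,0,0,0,0,4,0
"P004",23,1,0,1,1,4,2,1,0,0,0,1,0,1,1,1,1,1,1,0,1,1,1,2,2,2,0,0,1,1,1,2,2,4,0,3,3
"P005",17.9,1,1,1,0,3,2,0,4,2,4,1,0,2,3,3,0,0,2,2,3,2,4,0,2,0,2,4,4,2,4,4,2,0,0,1,1
"P005",21.1,1,1,0,3,3,0,4,3,3,3,1,1,0,0,1,1,1,0,3,0,0,0,1,0,1,1,3,1,1,1,1,0,0,0,2,2
"P006",10.8,1,1,2,1,4,1,2,2,3,3,4,0,0,2,0,1,1,0,0,0,0,0,1,4,1,0,1,2,4,2,3,2,4,2,2,4
"P006",12.8,1,1,4,1,3,3,4,3,0,2,2,1,2,0,1,0,3,1,3,3,0,0,1,2,0,3,1,4,3,4,1,1,1,1,0,1
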