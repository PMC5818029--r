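"id","outcome","caa_burden_sum","caa_burden_category","apoe_e4","apoe_e2","sah","flp","ich_location","strictly_lobar","age_years","sex","ich_volume_ml","anticoagulant_use"
"P001",0,0,"none",0,0,0,0,"lobar",1,78,"M",23,1
"P002",0,1,"mild",0,0,0,0,"lobar",1,78,"M",27,1
"P003",0,2,"mild",0,1,0,0,"lobar",1,79,"M",31,0
"P004",0,3,"mild",0,1,0,0,"lobar",1,79,"M",35,0
"P005",0,4,"mild",0,0,0,0,"lobar",0,80,"M",39,0
"P006",0,0,"none",0,0,0,0,"lobar",0,80,"M",44,0
"P007",0,1,"mild",0,0,0,0,"lobar",0,80,"M",48,0
"P008",0,2,"mild",0,0,0,0,"lobar",1,81,"M",52,0
"P009",0,3,"mild",0,0,0,0,"lobar",1,81,"M",56,0
"P010",0,4,"mild",0,0,0,0,"lobar",1,82,"M",60,0
"P011",0,0,"none",0,0,0,0,"lobar",1,82,"M",64,0
"P012",0,1,"mild",0,0,0,0,"lobar",1,82,"M",68,0
"P013",0,2,"mild",0,0,0,0,"lobar",1,83,"F",72,0
"P014",0,3,"mild",0,0,0,0,"lobar",1,83,"F",77,0
"P015",0,4,"mild",0,0,1,0,"lobar",1,84,"F",81,1
"P016",0,0,"none",0,0,1,0,"lobar",1,84,"F",85,1
"P017",0,1,"mild",0,1,1,0,"lobar",1,84,"F",89,0
"P018",0,2,"mild",0,0,1,0,"lobar",0,85,"F",93,0
"P019",0,3,"mild",0,0,1,0,"lobar",1,85,"F",97,0
"P020",0,4,"mild",0,0,1,0,"lobar",1,86,"F",101,0
"P021",0,0,"none",0,0,1,0,"lobar",1,86,"F",105,0
"P022",0,1,"mild",0,0,1,0,"lobar",1,86,"F",110,0
"P023",0,2,"mild",0,0,1,0,"lobar",1,87,"F",114,0
"P024",0,3,"mild",0,0,1,0,"lobar",1,87,"F",118,0
"P025",0,4,"mild",1,0,0,0,"lobar",1,88,"F",122,0
"P026",0,0,"none",1,0,1,0,"lobar",1,88,"F",126,0
"P027",1,5,"moderate",0,0,1,0,"lobar",1,79,"M",22,1
"P028",1,6,"moderate",0,0,1,0,"lobar",1,79,"M",25,1
"P029",1,7,"moderate",0,1,1,0,"lobar",1,79,"M",27,0
"P030",1,8,"moderate",0,1,1,0,"lobar",1,80,"M",30,0
"P031",1,9,"severe",0,0,1,0,"lobar",1,80,"M",33,0
"P032",1,10,"severe",0,0,1,0,"lobar",1,80,"M",36,0
"P033",1,11,"severe",0,0,1,0,"lobar",1,80,"M",38,0
"P034",1,12,"severe",0,0,1,0,"lobar",1,80,"M",41,0
"P035",1,5,"moderate",0,0,1,0,"lobar",1,80,"M",44,0
"P036",1,6,"moderate",0,0,1,1,"lobar",1,81,"M",46,1
"P037",1,7,"moderate",0,0,1,1,"lobar",1,81,"M",49,1
"P038",1,8,"moderate",0,1,1,1,"lobar",1,81,"F",52,0
"P039",1,9,"severe",0,1,1,1,"lobar",1,81,"F",55,0
"P040",1,10,"severe",0,0,1,1,"lobar",1,81,"F",57,0
"P041",1,11,"severe",0,0,1,1,"lobar",1,81,"F",60,0
"P042",1,12,"severe",0,0,1,1,"lobar",1,82,"F",63,0
"P043",1,5,"moderate",0,0,1,1,"lobar",1,82,"F",65,0
"P044",1,6,"moderate",0,0,1,1,"lobar",1,82,"F",68,0
"P045",1,7,"moderate",1,0,1,0,"lobar",1,82,"F",71,1
"P046",1,8,"moderate",1,1,1,0,"lobar",1,82,"F",74,0
"P047",1,9,"severe",1,1,1,0,"lobar",1,82,"F",76,0
"P048",1,10,"severe",1,1,1,0,"lobar",1,83,"F",79,0
"P049",1,11,"severe",1,0,1,0,"lobar",1,83,"F",82,0
"P050",1,12,"severe",1,0,1,0,"lobar",1,83,"F",84,0
"P051",1,5,"moderate",1,1,1,0,"lobar",1,83,"F",87,0
"P052",1,6,"moderate",1,1,1,0,"lobar",1,83,"F",90,0
"P053",1,7,"moderate",1,0,1,0,"lobar",1,83,"F",93,0
"P054",1,8,"moderate",1,0,1,1,"lobar",1,84,"F",95,0
"P055",1,9,"severe",1,0,1,1,"lobar",1,84,"F",98,0
"P056",1,10,"severe",1,0,1,1,"lobar",1,84,"F",101,0
"P057",1,11,"severe",1,0,1,1,"lobar",1,84,"F",103,0
"P058",1,12,"severe",1,0,1,1,"lobar",1,84,"F",106,0
"P059",1,5,"moderate",1,1,0,0,"lobar",1,84,"F",109,0
"P060",1,6,"moderate",1,1,0,0,"lobar",1,85,"F",112,0
"P061",1,7,"moderate",1,0,0,0,"lobar",1,85,"F",114,0
"P062",1,8,"moderate",1,0,0,0,"lobar",1,85,"F",117,0
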