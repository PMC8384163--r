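"site","measure","value","reference"
"Nashville","volume",90.8,89
"Austin","volume",87.4,89
"Denver","volume",91,89
"Chicago","volume",91.2,89
"Melbourne","volume",89.5,89
"Nashville","mtr",0.383,
"Austin","mtr",0.378,
"Denver","mtr",0.384,
"Chicago","mtr",0.317,
"Melbourne","mtr",0.326,
"Nashville","adc",0.0014,
"Austin","adc",0.0014,
"Denver","adc",0.0013,
"Chicago","adc",0.0013,
"Melbourne","adc",0.0015,
"Nashville","t1_vial_1",468,500
"Austin","t1_vial_1",500,500
"Denver","t1_vial_1",494,500
"Chicago","t1_vial_1",454,500
"Melbourne","t1_vial_1",447,500
"Nashville","t1_vial_2",948,1000
"Austin","t1_vial_2",1038,1000
"Denver","t1_vial_2",1020,1000
"Chicago","t1_vial_2",1141,1000
"Melbourne","t1_vial_2",897,1000
"Nashville","t1_vial_3",1284,1250
"Austin","t1_vial_3",1250,1250
"Denver","t1_vial_3",1256,1250
"Chicago","t1_vial_3",1375,1250
"Melbourne","t1_vial_3",1092,1250
"Nashville","t1_vial_4",1570,1500
"Austin","t1_vial_4",1550,1500
"Denver","t1_vial_4",1600,1500
"Chicago","t1_vial_4",1625,1500
"Melbourne","t1_vial_4",1354,1500
"Nashville","fat_fraction",96.7,
"Austin","fat_fraction",95.9,
"Denver","fat_fraction",,
"Chicago","fat_fraction",96.2,
"Melbourne","fat_fraction",95.6,
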