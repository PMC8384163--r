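"subject","site","measure","value"
"Volunteer 1","Austin","adc",0.0010299
"Volunteer 1","Chicago","adc",0.0012272
"Volunteer 1","Denver","adc",0.0011715
"Volunteer 1","Nashville","adc",0.0011888
"Volunteer 1","Austin","hep_fat_fraction",0.0296
"Volunteer 1","Chicago","hep_fat_fraction",0.0312
"Volunteer 1","Denver","hep_fat_fraction",
"Volunteer 1","Nashville","hep_fat_fraction",0.0422
"Volunteer 1","Austin","mtr",0.44421
"Volunteer 1","Chicago","mtr",0.24861
"Volunteer 1","Denver","mtr",0.44516
"Volunteer 1","Nashville","mtr",0.37469
"Volunteer 1","Austin","panc_fat_fraction",0.13584
"Volunteer 1","Chicago","panc_fat_fraction",0.18757
"Volunteer 1","Denver","panc_fat_fraction",
"Volunteer 1","Nashville","panc_fat_fraction",0.1472
"Volunteer 1","Austin","pvi",0.79655
"Volunteer 1","Chicago","pvi",0.90742
"Volunteer 1","Denver","pvi",0.77619
"Volunteer 1","Nashville","pvi",1.0862
"Volunteer 1","Austin","surface_to_volume",0.10107
"Volunteer 1","Chicago","surface_to_volume",0.095063
"Volunteer 1","Denver","surface_to_volume",0.10482
"Volunteer 1","Nashville","surface_to_volume",0.1017
"Volunteer 1","Austin","t1",890.77
"Volunteer 1","Chicago","t1",1043.3
"Volunteer 1","Denver","t1",866.19
"Volunteer 1","Nashville","t1",958.61
"Volunteer 1","Austin","volume",59.616
"Volunteer 1","Chicago","volume",67.914
"Volunteer 1","Denver","volume",60.768
"Volunteer 1","Nashville","volume",81.297
"Volunteer 2","Austin","adc",0.0012671
"Volunteer 2","Chicago","adc",0.0014198
"Volunteer 2","Denver","adc",0.0014773
"Volunteer 2","Nashville","adc",0.0012611
"Volunteer 2","Austin","hep_fat_fraction",
"Volunteer 2","Chicago","hep_fat_fraction",0.024
"Volunteer 2","Denver","hep_fat_fraction",
"Volunteer 2","Nashville","hep_fat_fraction",0.0465
"Volunteer 2","Austin","mtr",0.30807
"Volunteer 2","Chicago","mtr",0.055648
"Volunteer 2","Denver","mtr",0.31042
"Volunteer 2","Nashville","mtr",0.41664
"Volunteer 2","Austin","panc_fat_fraction",
"Volunteer 2","Chicago","panc_fat_fraction",0.060248
"Volunteer 2","Denver","panc_fat_fraction",
"Volunteer 2","Nashville","panc_fat_fraction",0.020894
"Volunteer 2","Austin","pvi",1.09808
"Volunteer 2","Chicago","pvi",1.07488
"Volunteer 2","Denver","pvi",1.294076
"Volunteer 2","Nashville","pvi",1.081765
"Volunteer 2","Austin","surface_to_volume",0.10107
"Volunteer 2","Chicago","surface_to_volume",0.11043
"Volunteer 2","Denver","surface_to_volume",0.10595
"Volunteer 2","Nashville","surface_to_volume",0.1118
"Volunteer 2","Austin","t1",1236.4
"Volunteer 2","Chicago","t1",1055.5
"Volunteer 2","Denver","t1",1311.6
"Volunteer 2","Nashville","t1",1108.1
"Volunteer 2","Austin","volume",74.214
"Volunteer 2","Chicago","volume",73.134
"Volunteer 2","Denver","volume",87.93
"Volunteer 2","Nashville","volume",73.602
"Volunteer 3","Austin","adc",0.001267
"Volunteer 3","Chicago","adc",0.0010943
"Volunteer 3","Denver","adc",0.0011184
"Volunteer 3","Nashville","adc",0.0012716
"Volunteer 3","Austin","hep_fat_fraction",0.0293
"Volunteer 3","Chicago","hep_fat_fraction",0.0185
"Volunteer 3","Denver","hep_fat_fraction",
"Volunteer 3","Nashville","hep_fat_fraction",0.0394
"Volunteer 3","Austin","mtr",0.28954
"Volunteer 3","Chicago","mtr",
"Volunteer 3","Denver","mtr",0.34684
"Volunteer 3","Nashville","mtr",0.40765
"Volunteer 3","Austin","panc_fat_fraction",0.13369
"Volunteer 3","Chicago","panc_fat_fraction",0.12877
"Volunteer 3","Denver","panc_fat_fraction",
"Volunteer 3","Nashville","panc_fat_fraction",0.13
"Volunteer 3","Austin","pvi",1.29617
"Volunteer 3","Chicago","pvi",1.1852
"Volunteer 3","Denver","pvi",1.30389
"Volunteer 3","Nashville","pvi",1.1893
"Volunteer 3","Austin","surface_to_volume",0.086092
"Volunteer 3","Chicago","surface_to_volume",0.095138
"Volunteer 3","Denver","surface_to_volume",0.075841
"Volunteer 3","Nashville","surface_to_volume",0.087008
"Volunteer 3","Austin","t1",874.06
"Volunteer 3","Chicago","t1",989.93
"Volunteer 3","Denver","t1",818.81
"Volunteer 3","Nashville","t1",1168.1
"Volunteer 3","Austin","volume",122.29
"Volunteer 3","Chicago","volume",112.9
"Volunteer 3","Denver","volume",127.75
"Volunteer 3","Nashville","volume",112.75
"Volunteer 4","Austin","adc",0.0014217
"Volunteer 4","Chicago","adc",0.0011398
"Volunteer 4","Denver","adc",0.0011917
"Volunteer 4","Nashville","adc",0.0013227
"Volunteer 4","Austin","hep_fat_fraction",0.0163
"Volunteer 4","Chicago","hep_fat_fraction",0.0269
"Volunteer 4","Denver","hep_fat_fraction",
"Volunteer 4","Nashville","hep_fat_fraction",0.0298
"Volunteer 4","Austin","mtr",0.32639
"Volunteer 4","Chicago","mtr",0.085408
"Volunteer 4","Denver","mtr",0.3998
"Volunteer 4","Nashville","mtr",0.249
"Volunteer 4","Austin","panc_fat_fraction",0.078579
"Volunteer 4","Chicago","panc_fat_fraction",0.13843
"Volunteer 4","Denver","panc_fat_fraction",
"Volunteer 4","Nashville","panc_fat_fraction",0.077119
"Volunteer 4","Austin","pvi",0.80677
"Volunteer 4","Chicago","pvi",0.97
"Volunteer 4","Denver","pvi",0.84645
"Volunteer 4","Nashville","pvi",0.7781
"Volunteer 4","Austin","surface_to_volume",0.11427
"Volunteer 4","Chicago","surface_to_volume",0.11338
"Volunteer 4","Denver","surface_to_volume",0.11303
"Volunteer 4","Nashville","surface_to_volume",0.11663
"Volunteer 4","Austin","t1",897.35
"Volunteer 4","Chicago","t1",918.05
"Volunteer 4","Denver","t1",868.17
"Volunteer 4","Nashville","t1",901.82
"Volunteer 4","Austin","volume",60.381
"Volunteer 4","Chicago","volume",70.839
"Volunteer 4","Denver","volume",63.351
"Volunteer 4","Nashville","volume",57.177
"Volunteer 5","Austin","adc",0.00094109
"Volunteer 5","Chicago","adc",0.0010638
"Volunteer 5","Denver","adc",0.0008776
"Volunteer 5","Nashville","adc",0.0010012
"Volunteer 5","Austin","hep_fat_fraction",0.1111
"Volunteer 5","Chicago","hep_fat_fraction",0.1686
"Volunteer 5","Denver","hep_fat_fraction",
"Volunteer 5","Nashville","hep_fat_fraction",0.1381
"Volunteer 5","Austin","mtr",0.40804
"Volunteer 5","Chicago","mtr",0.089641
"Volunteer 5","Denver","mtr",0.39628
"Volunteer 5","Nashville","mtr",0.39885
"Volunteer 5","Austin","panc_fat_fraction",0.2386
"Volunteer 5","Chicago","panc_fat_fraction",0.20345
"Volunteer 5","Denver","panc_fat_fraction",
"Volunteer 5","Nashville","panc_fat_fraction",0.23798
"Volunteer 5","Austin","pvi",1.19367
"Volunteer 5","Chicago","pvi",1.0294
"Volunteer 5","Denver","pvi",1.04345
"Volunteer 5","Nashville","pvi",0.9721
"Volunteer 5","Austin","surface_to_volume",0.083718
"Volunteer 5","Chicago","surface_to_volume",0.081018
"Volunteer 5","Denver","surface_to_volume",0.070601
"Volunteer 5","Nashville","surface_to_volume",0.075479
"Volunteer 5","Austin","t1",839.37
"Volunteer 5","Chicago","t1",707.06
"Volunteer 5","Denver","t1",830.25
"Volunteer 5","Nashville","t1",676.91
"Volunteer 5","Austin","volume",116.41
"Volunteer 5","Chicago","volume",100.39
"Volunteer 5","Denver","volume",103.18
"Volunteer 5","Nashville","volume",96.57
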