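sample_id	series	day	gene	role	quantity
G6_d0	G6	0	REF1	reference	12386.1603980959
G6_d0	G6	0	REF2	reference	7893.68690537572
G6_d0	G6	0	TGT_flat	target	697.95408501044
G6_d0	G6	0	TGT_late	target	255.983609973594
G6_d0	G6	0	TGT_early	target	0
G6_d3	G6	3	REF1	reference	6147.6656495973
G6_d3	G6	3	REF2	reference	5339.13212632936
G6_d3	G6	3	TGT_flat	target	333.021346079579
G6_d3	G6	3	TGT_late	target	133.471932276994
G6_d3	G6	3	TGT_early	target	273.413501958697
G6_d7	G6	7	REF1	reference	12239.7250692845
G6_d7	G6	7	REF2	reference	13367.1339840475
G6_d7	G6	7	TGT_flat	target	946.834995655352
G6_d7	G6	7	TGT_late	target	730.793806853968
G6_d7	G6	7	TGT_early	target	177.350976716861
G6_d15	G6	15	REF1	reference	4957.68148624763
G6_d15	G6	15	REF2	reference	4381.71781175315
G6_d15	G6	15	TGT_flat	target	532.597305744477
G6_d15	G6	15	TGT_late	target	829.750744662395
G6_d15	G6	15	TGT_early	target	0
G6_d21	G6	21	REF1	reference	7383.84611703173
G6_d21	G6	21	REF2	reference	4324.666632529
G6_d21	G6	21	TGT_flat	target	517.865099754296
G6_d21	G6	21	TGT_late	target	1649.58150766926
G6_d21	G6	21	TGT_early	target	0
G6NR_d0	G6NR	0	REF1	reference	10674.8022350596
G6NR_d0	G6NR	0	REF2	reference	9243.04423713959
G6NR_d0	G6NR	0	TGT_flat	target	660.214842859096
G6NR_d0	G6NR	0	TGT_late	target	273.64299725198
G6NR_d0	G6NR	0	TGT_early	target	0
G6NR_d3	G6NR	3	REF1	reference	8009.44645749642
G6NR_d3	G6NR	3	REF2	reference	4244.52782564258
G6NR_d3	G6NR	3	TGT_flat	target	320.155389481279
G6NR_d3	G6NR	3	TGT_late	target	235.885477396831
G6NR_d3	G6NR	3	TGT_early	target	263.30524661539
G6NR_d7	G6NR	7	REF1	reference	8559.72374049249
G6NR_d7	G6NR	7	REF2	reference	8197.73121908697
G6NR_d7	G6NR	7	TGT_flat	target	381.749748002184
G6NR_d7	G6NR	7	TGT_late	target	297.382344535805
G6NR_d7	G6NR	7	TGT_early	target	165.998947990464
G6NR_d15	G6NR	15	REF1	reference	9141.80144643587
G6NR_d15	G6NR	15	REF2	reference	6200.492256272
G6NR_d15	G6NR	15	TGT_flat	target	409.801803294334
G6NR_d15	G6NR	15	TGT_late	target	752.619471790349
G6NR_d15	G6NR	15	TGT_early	target	0
G6NR_d21	G6NR	21	REF1	reference	5896.53304828727
G6NR_d21	G6NR	21	REF2	reference	8278.07620795976
G6NR_d21	G6NR	21	TGT_flat	target	341.052473105459
G6NR_d21	G6NR	21	TGT_late	target	2220.50410550242
G6NR_d21	G6NR	21	TGT_early	target	0
G2_d0	G2	0	REF1	reference	11363.784844854
G2_d0	G2	0	REF2	reference	5753.33094397995
G2_d0	G2	0	TGT_flat	target	617.217711663036
G2_d0	G2	0	TGT_late	target	163.458581676349
G2_d0	G2	0	TGT_early	target	0
G2_d3	G2	3	REF1	reference	10421.6042984222
G2_d3	G2	3	REF2	reference	6387.95880145645
G2_d3	G2	3	TGT_flat	target	422.20946073186
G2_d3	G2	3	TGT_late	target	188.273848819021
G2_d3	G2	3	TGT_early	target	338.473546050405
G2_d7	G2	7	REF1	reference	8268.81021566463
G2_d7	G2	7	REF2	reference	9858.25278568962
G2_d7	G2	7	TGT_flat	target	449.309670678367
G2_d7	G2	7	TGT_late	target	386.734904040636
G2_d7	G2	7	TGT_early	target	165.43306265112
G2_d15	G2	15	REF1	reference	10246.6889287096
G2_d15	G2	15	REF2	reference	8318.5356644986
G2_d15	G2	15	TGT_flat	target	616.239780294133
G2_d15	G2	15	TGT_late	target	1673.34968224411
G2_d15	G2	15	TGT_early	target	0
G2_d21	G2	21	REF1	reference	13100.1164350512
G2_d21	G2	21	REF2	reference	3279.24465004986
G2_d21	G2	21	TGT_flat	target	436.322888229272
G2_d21	G2	21	TGT_late	target	1442.11237816712
G2_d21	G2	21	TGT_early	target	0
G12_d0	G12	0	REF1	reference	9658.70616736968
G12_d0	G12	0	REF2	reference	8690.28472011297
G12_d0	G12	0	TGT_flat	target	593.128740804647
G12_d0	G12	0	TGT_late	target	156.239276081664
G12_d0	G12	0	TGT_early	target	0
G12_d3	G12	3	REF1	reference	12968.2586476956
G12_d3	G12	3	REF2	reference	7503.28792076789
G12_d3	G12	3	TGT_flat	target	764.534638439392
G12_d3	G12	3	TGT_late	target	374.210808585764
G12_d3	G12	3	TGT_early	target	510.622265381197
G12_d7	G12	7	REF1	reference	10011.6928787894
G12_d7	G12	7	REF2	reference	6639.46283187548
G12_d7	G12	7	TGT_flat	target	437.830401161629
G12_d7	G12	7	TGT_late	target	480.932348843189
G12_d7	G12	7	TGT_early	target	120.798362467308
G12_d15	G12	15	REF1	reference	11787.1178337391
G12_d15	G12	15	REF2	reference	10237.6951662573
G12_d15	G12	15	TGT_flat	target	378.609553284167
G12_d15	G12	15	TGT_late	target	676.701295551726
G12_d15	G12	15	TGT_early	target	0
G12_d21	G12	21	REF1	reference	8209.8694994394
G12_d21	G12	21	REF2	reference	5037.79164992947
G12_d21	G12	21	TGT_flat	target	827.47753481358
G12_d21	G12	21	TGT_late	target	2024.79650837861
G12_d21	G12	21	TGT_early	target	0
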