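snp_id	z
snp1	3.053198
snp2	5.612264
snp3	17.377193
snp4	3.464097
snp5	1.588898
snp6	1.806248
snp7	-0.153365
snp8	-0.501174
snp9	-0.139608
snp10	-0.804423
snp11	-0.302832
snp12	-0.464141
snp13	1.964644
snp14	0.742114
snp15	-1.590559
snp16	-0.906335
snp17	-0.761524
snp18	-0.518186
snp19	-0.067162
snp20	1.072688
snp21	1.732505
snp22	0.290351
snp23	0.833164
snp24	-1.469664
snp25	1.132639
snp26	2.031551
snp27	0.720255
snp28	0.314009
snp29	-0.541547
snp30	-0.88687
snp31	-0.765759
snp32	-1.146128
snp33	2.507848
snp34	1.076028
snp35	1.572867
snp36	0.207549
snp37	-0.374249
snp38	-0.201765
snp39	-2.019918
snp40	-0.231863
snp41	1.329265
snp42	0.197174
snp43	0.322196
snp44	0.375146
snp45	-0.483918
snp46	1.189198
snp47	1.989949
snp48	1.610276
snp49	0.227005
snp50	-0.674305
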