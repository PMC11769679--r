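snp_id	annot1	annot2	annot3	annot4	annot5
snp1	1.5485	-0.695	-0.1209	-0.4694	1.3838
snp2	-0.0145	-1.1136	1.3701	-1.7234	-0.0687
snp3	-0.2656	-1.9539	-1.0888	1.3336	2.2142
snp4	1.6144	-0.7643	-1.6978	-0.793	0.0761
snp5	0.1382	1.5505	-0.9371	1.0199	0.3514
snp6	0.965	-0.3766	1.7461	-0.2501	0.9453
snp7	-0.4207	1.5067	-1.5402	1.7623	-0.9906
snp8	0.6211	-0.874	0.1701	0.4329	-0.1615
snp9	-0.753	0.7144	0.1638	-0.5822	-0.0465
snp10	-1.0497	-2.0727	0.7159	-0.5123	0.4267
snp11	-0.4112	0.9595	-0.8841	-0.6327	-0.094
snp12	0.6405	-0.2914	0.608	-2.5989	0.1755
snp13	0.4241	0.799	0.8818	1.1051	0.3348
snp14	-1.1769	0.2052	0.7239	-0.8401	-0.953
snp15	0.1572	-0.2503	1.12	-0.9354	-1.1553
snp16	1.9574	-1.3733	0.6819	-0.5338	0.1723
snp17	1.6694	0.3239	-2.178	0.5216	-2.0041
snp18	-0.0387	-0.1297	-0.5462	-0.063	-1.52
snp19	-1.9418	1.8038	-1.1596	0.1963	0.2635
snp20	-0.7563	1.0722	0.1014	-2.0247	-0.3521
snp21	-0.1977	-2.4897	-0.1171	0.1767	1.5458
snp22	0.787	0.4978	-0.2258	1.1732	1.2939
snp23	0.5097	-0.5847	0.7935	-0.1808	-0.5246
snp24	-0.5207	-0.9011	0.6365	1.2086	-0.4027
snp25	0.6489	-0.6001	0.4046	0.2818	-0.2926
snp26	-0.2455	0.6499	0.1739	-0.9316	2.4381
snp27	-0.9408	0.6743	-0.3284	-0.0043	-0.2764
snp28	-0.6725	0.7588	-0.9565	-0.4476	-1.7402
snp29	1.021	-0.9643	1.8022	0.6277	0.4645
snp30	-0.218	-3.7657	-0.7294	0.2158	-0.3287
snp31	1.8128	-0.5762	-1.2264	0.4084	-0.9659
snp32	-0.3178	-2.0084	-0.5932	-0.2808	0.2728
snp33	1.3659	-0.1682	-0.0288	1.097	0.7422
snp34	-0.0151	-0.9924	-0.6701	0.6261	0.1525
snp35	1.1418	-0.4996	-0.2358	1.5883	-1.1285
snp36	-2.255	-0.9077	2.4861	-0.2785	0.0227
snp37	0.2386	-1.1155	-0.0455	0.769	-0.9081
snp38	0.1721	-0.6708	0.6887	0.9035	-1.7215
snp39	0.4007	-1.91	-0.336	-1.2718	-1.0424
snp40	1.2776	-0.2989	0.2534	0.561	-0.7209
snp41	1.2121	-0.188	1.1097	0.398	-1.0835
snp42	0.2601	0.3306	-0.3648	-0.6232	-0.6016
snp43	-1.5475	0.5633	1.7091	0.4007	0.3726
snp44	-0.5375	-0.4547	1.6303	0.5223	-0.3686
snp45	1.2642	1.1225	0.0012	1.6774	0.5565
snp46	1.178	-1.1039	-1.4818	-1.0798	1.4841
snp47	0.4299	0.3572	1.2822	-0.7581	-0.2956
snp48	0.1319	0.5122	-1.9382	-0.6696	-0.7045
snp49	2.144	-0.2162	0.6297	0.4505	-0.1435
snp50	0.4367	0.1452	2.3674	1.1173	-1.4683
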