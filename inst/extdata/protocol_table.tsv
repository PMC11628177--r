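Is_diff	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
b-values	0	0.100_0.228	0.325	0.771	0.771	0.771	1.224	1.224	1.303	1.303	1.505	1.827	1.827	2.192	2.192	2.069	2.069	2.602	2.602
Ndir	0	0	4	4	6	5	7	4	5	11	7	4	4	3	7	6	9	5	9
Ndir_spherical	0	1	1	3	3	2	3	1	0	3	4	2	1	1	5	1	3	1	5
b_Δ	0	0	0_-0.5_1	0.5	0_1_-0.5	0_1_-0.5	0_0.5_1_-0.5	0_1_-0.5	0.5_1	0_1_-0.5	0_-0.5_1_0.5	0_-0.5_1	0_1	0_1	0_0.5_1	0_0.5_1	0_1_-0.5	0_1	0_1
freq_waveform	0	1	1	1	1	1	1	1	1_2	1_2	1	1	1	1	1	1_2	1_2	1	1
N_b0	0	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1	1
τE+	0_4_10	0_12_40	0_16_36	0	0_25	0	0	0_26	0	0	0	15	0	0_15	0	0	0	0	0
τR+	1100_1800_3000	1000_2500	1200	2000	2000	1100	2000	3500	2000	2500	1700	2300	1100	1500	3000	2500	3200	2500	3500
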