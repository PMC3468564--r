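population	n	p_H	p_C1	p_C2	obs_HH	obs_HC1	obs_HC2	obs_C1C1	obs_C1C2	obs_C2C2	exp_HH	exp_HC1	exp_HC2	exp_C1C1	exp_C1C2	exp_C2C2
Taiwanese	1244	0.72	0.17	0.11	0.52	0.24	0.16	0.04	0.03	0.01	0.52	0.24	0.16	0.03	0.04	0.01
JPT	87	0.71	0.19	0.10	0.51	0.27	0.15	0.03	0.03	0.01	0.50	0.27	0.14	0.04	0.04	0.01
CHB	86	0.70	0.20	0.10	0.49	0.29	0.14	0.03	0.05	0.00	0.49	0.28	0.14	0.04	0.04	0.01
CEU	174	0.45	0.15	0.40	0.21	0.13	0.36	0.02	0.12	0.16	0.20	0.14	0.36	0.02	0.12	0.16
ASW	83	0.42	0.19	0.39	0.15	0.17	0.37	0.02	0.17	0.12	0.17	0.16	0.33	0.04	0.15	0.15
GIH	87	0.40	0.29	0.31	0.13	0.28	0.26	0.06	0.18	0.08	0.16	0.23	0.25	0.08	0.18	0.10
YRI	176	0.39	0.27	0.34	0.18	0.19	0.24	0.07	0.21	0.11	0.15	0.21	0.27	0.07	0.18	0.12
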