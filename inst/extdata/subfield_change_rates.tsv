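region	index	mean_stable	sd_stable	mean_converter	sd_converter	p_value	cohens_d
presubiculum	volume	-2.73	8.38	-7.34	6.46	0.00001	0.61848
subiculum	volume	-3.96	6.13	-7.78	5.81	0.00001	0.64324
CA1	volume	-2.74	5.14	-4.84	4.99	0.00154	0.41515
CA3	volume	-3.21	7.99	-6.13	6.68	0.00233	0.39884
CA4	volume	-3.07	6.02	-5.34	5.01	0.00167	0.41205
GC-ML-DG	volume	-3.52	6.07	-5.61	4.86	0.00365	0.38056
molecular layer	volume	-3.6	6.23	-6.62	4.71	0.00003	0.54958
hippocampal fissure	volume	0.57	7.83	-3.34	8.93	0.00037	0.46771
hippocampal tail	volume	-2.26	8.36	-4.87	6.3	0.00681	0.35392
presubiculum	surface_area	-2.23	4.95	-4.75	4.62	0.00006	0.52750
subiculum	surface_area	-2.59	4.14	-5.68	4.16	0.00001	0.74995
CA1	surface_area	-2.36	4.58	-4.36	3.93	0.00003	0.47154
CA3	surface_area	-3.22	5.58	-5.62	5.29	0.00075	0.44230
CA4	surface_area	-2.91	4.39	-5.01	3.89	0.00045	0.50678
GC-ML-DG	surface_area	-3.36	4.87	-4.87	4.23	0.00109	0.33237
molecular layer	surface_area	-3.25	5.38	-5.71	4.54	0.00017	0.49474
hippocampal fissure	surface_area	2.53	13.24	-3.96	13.42	0.000205	0.48880
hippocampal tail	surface_area	-1.61	4.08	-4.06	4.43	0.00001	0.57654
presubiculum	rpc	3.26	7.82	1.24	9.65	0.07571	0.23127
subiculum	rpc	-0.24	7.74	1.87	8.92	0.05146	0.25377
CA1	rpc	0.17	7.1	2.59	8.33	0.01595	0.31467
CA3	rpc	4.23	14.62	3.61	14.42	0.74307	0.04254
CA4	rpc	13.0	54.5	14.3	58.17	0.85797	0.02323
GC-ML-DG	rpc	3.5	20.75	4.35	19.91	0.74702	0.04187
molecular layer	rpc	4.08	23.04	7.0	24.87	0.34714	0.12212
hippocampal fissure	rpc	2.14	19.4	2.85	19.14	0.77527	0.03705
hippocampal tail	rpc	2.12	11.1	2.11	12.34	0.99021	0.00159
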