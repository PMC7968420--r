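rank	region	index	p_value	p_censored
1	subiculum	surface_area	0.00001	TRUE
2	subiculum	volume	0.00001	TRUE
3	presubiculum	volume	0.00001	TRUE
4	hippocampal tail	surface_area	0.00001	FALSE
5	molecular layer	volume	0.00003	FALSE
6	presubiculum	surface_area	0.00006	FALSE
7	CA4	surface_area	0.00012	FALSE
8	molecular layer	surface_area	0.00017	FALSE
9	hippocampal fissure	surface_area	0.00021	FALSE
10	CA1	surface_area	0.00034	FALSE
11	hippocampal fissure	volume	0.00038	FALSE
12	CA3	surface_area	0.00076	FALSE
13	CA1	volume	0.00155	FALSE
14	CA4	volume	0.00168	FALSE
15	CA3	volume	0.00234	FALSE
16	GC-ML-DG	volume	0.00366	FALSE
17	presubiculum	curv_min	0.00373	FALSE
18	hippocampal tail	volume	0.00681	FALSE
19	CA1	curv_max	0.00969	FALSE
20	GC-ML-DG	surface_area	0.01097	FALSE
21	CA1	rpc	0.01596	FALSE
22	subiculum	rpc	0.05146	FALSE
23	presubiculum	curv_max	0.06049	FALSE
24	CA4	curv_min	0.06766	FALSE
25	presubiculum	rpc	0.07571	FALSE
26	molecular layer	curv_max	0.11261	FALSE
27	hippocampal tail	curv_max	0.25083	FALSE
28	hippocampal fissure	curv_max	0.29224	FALSE
29	molecular layer	rpc	0.34715	FALSE
30	CA4	curv_max	0.41302	FALSE
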