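index	reactants	products	rate_constant
1	LPS + TLR4	LPS_TLR4	1.28e-6
2	LPS_TLR4	LPS_bind + TLR4_bind	1.0
3	TLR4_bind + TIRAP	TLR4_bind_TIRAP	9.3e-6
4	TLR4_bind_TIRAP	TLR4_bind + TIRAP_bind	1.0
5	TIRAP_bind + MyD88	TIRAP_bind_MyD88	6.0e-5
6	TIRAP_bind_MyD88	TIRAP_bind + MyD88_bind	1.0
7	MyD88_bind + IRAK1	MyD88_bind_IRAK1	2.92e-5
8	MyD88_bind_IRAK1	MyD88_bind + IRAK1_bind	1.0
9	MyD88_bind + IRAK4	MyD88_bind_IRAK4	1.2e-5
10	MyD88_bind_IRAK4	MyD88_bind + IRAK4_bind	1.0
11	IRAK1_bind + TRAF6	IRAK1_bind_TRAF6	7.0e-6
12	IRAK1_bind_TRAF6	IRAK1_bind + TRAF6_bind	1.0
13	TIRAP_bind	TIRAP_drop	5.0e-3
14	MyD88_bind	MyD88_drop	8.0e-3
15	IRAK1_bind	IRAK1_drop	4.0e-3
16	IRAK4_bind	IRAK4_drop	3.0e-3
17	TRAF6_bind	TRAF6_drop	8.0e-4
18	MyD88_drop + TRAF6_drop	MyD88_drop_TRAF6_drop	1.0e-7
19	MyD88_drop_TRAF6_drop	MyD88_drop + TRAF6_BIND	1.0
20	TRAF6_BIND + MyD88_drop	TRAF6_BIND_MyD88_drop	1.07e-5
21	TRAF6_BIND_MyD88_drop	TRAF6_BIND + MyD88_BIND	1.0
22	TRAF6_BIND + IRAK1_drop	TRAF6_BIND_IRAK1_drop	6.0e-5
23	TRAF6_BIND_IRAK1_drop	TRAF6_BIND + IRAK1_BIND	1.0
24	TRAF6_BIND + IRAK4_drop	TRAF6_BIND_IRAK4_drop	2.92e-5
25	TRAF6_BIND_IRAK4_drop	TRAF6_BIND + IRAK4_BIND	1.0
26	TRAF6_BIND	TRAF6_DROP	4.0e-4
27	MyD88_BIND	MyD88_DROP	5.0e-4
28	IRAK1_BIND	IRAK1_DROP	1.5e-3
29	IRAK4_BIND	IRAK4_DROP	1.0e-3
30	TLR4_bind + MyD88	TLR4_bind_MyD88	1.0e-5
31	TLR4_bind_MyD88	TLR4_bind + MyD88_binda	1.0
32	MyD88_binda + IRAK1	MyD88_binda_IRAK1	1.8e-6
33	MyD88_binda_IRAK1	MyD88_binda + IRAK1_binda	1.0
34	MyD88_binda + IRAK4	MyD88_binda_IRAK4	5.0e-7
35	MyD88_binda_IRAK4	MyD88_binda + IRAK4_binda	1.0
36	IRAK1_binda	IRAK1_dropa	1.4e-3
37	IRAK4_binda	IRAK4_dropa	1.2e-3
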