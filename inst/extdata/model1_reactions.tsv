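index	reactants	products	rate_constant
1	LPS + TLR4	LPS_TLR4	1.28e-6
2	LPS_TLR4	LPS_bind + TLR4_bind	1.0
3	TLR4_bind + TIRAP	TLR4_bind_TIRAP	9.3e-6
4	TLR4_bind_TIRAP	TLR4_bind + TIRAP_bind	1.0
5	TIRAP_bind + MyD88	TIRAP_bind_MyD88	5.6e-5
6	TIRAP_bind_MyD88	TIRAP_bind + MyD88_bind	1.0
7	MyD88_bind + IRAK1	MyD88_bind_IRAK1	4.75e-5
8	MyD88_bind_IRAK1	MyD88_bind + IRAK1_bind	1.0
9	MyD88_bind + IRAK4	MyD88_bind_IRAK4	7.98e-6
10	MyD88_bind_IRAK4	MyD88_bind + IRAK4_bind	1.0
11	IRAK1_bind + TRAF6	IRAK1_bind_TRAF6	7.0e-6
12	IRAK1_bind_TRAF6	IRAK1_bind + TRAF6_bind	1.0
13	TIRAP_bind	TIRAP_drop	5.0e-3
14	MyD88_bind	MyD88_drop	1.0e-2
15	IRAK1_bind	IRAK1_drop	2.2e-3
16	IRAK4_bind	IRAK4_drop	5.62e-4
17	TRAF6_bind	TRAF6_drop	1.96e-3
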