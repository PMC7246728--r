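name	initial_amount
LPS	500
TLR4	20
TIRAP	100
MyD88	1000
IRAK1	100
IRAK4	100
TRAF6	100
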