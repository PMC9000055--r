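gene	case_carriers	case_n	control_carriers	control_n
CDHR1	3	622	119	10865
CHM	3	622	37	10865
CRX	1	622	7	10865
ELOVL4	1	622	6	10865
PROM1	7	622	71	10865
PRPH2	1	622	31	10865
ROM1	8	622	37	10865
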