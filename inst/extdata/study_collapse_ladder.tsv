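maf_max	case_carriers	case_n	control_carriers	control_n
0.005	24	622	306	10865
0.001	15	622	186	10865
0.0001	10	622	105	10865
0.00001	2	622	36	10865
nd	2	622	35	10865
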