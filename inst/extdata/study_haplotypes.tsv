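haplotype	aminoacids	discovery_all	discovery_hypomorph	discovery_g1961e	replication_all	replication_hypomorph	replication_g1961e
G-A-G	EKG	937	139	220	613	102	107
C-G-A	QRD	136	14	52	99	8	23
C-A-A	QKD	151	13	34	95	10	10
G-A-A	EKD	19	0	0	6	0	0
G-G-A	ERD	0	0	0	2	0	0
C-A-G	QKG	1	0	0	1	0	0
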