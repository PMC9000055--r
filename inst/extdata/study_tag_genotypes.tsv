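cohort	group	n	pct_minor_hom	pct_het	pct_major_hom
discovery	all_patients	622	5.5	38.6	55.9
discovery	gnomad_matched_controls	43029	4.5	33.1	62.4
discovery	hypomorph	83	0	32.5	67.5
discovery	minus_hypomorph	539	6.3	39.5	54.2
discovery	g1961e	153	7.8	40.5	51.6
discovery	minus_g1961e	469	4.7	38	57.3
discovery	hypomorph_ext	97	0	29.9	70.1
discovery	minus_hypomorph_ext	525	6.5	40.2	53.3
replication	all_patients	408	7.3	34.8	57.8
replication	gnomad_matched_controls	43029	4.5	33.1	62.4
replication	hypomorph	60	0	30	70
replication	minus_hypomorph	348	8.6	35.6	55.7
replication	g1961e	70	7.1	32.9	60
replication	minus_g1961e	338	7.4	35.2	57.4
combined	all_patients	1030	6.2	37.1	56.7
combined	gnomad_matched_controls	43029	4.5	33.1	62.4
combined	hypomorph	143	0	31.5	68.5
combined	minus_hypomorph	887	7.2	38	54.8
combined	g1961e	223	7.6	38.1	54.3
combined	minus_g1961e	807	5.8	36.8	57.4
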