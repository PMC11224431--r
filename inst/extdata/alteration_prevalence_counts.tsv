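feature	level	variant_class	age_group	n_detected	denominator
KRAS	gene	snv	all	1998	7179
RBM10	gene	snv	all	530	7179
EML4-ALK Fusion	variant	fusion_skipping	all	85	6304
ALK	gene	fusion_skipping	all	100	6304
MET Exon 14 Skipping	gene	fusion_skipping	all	196	6304
MET Exon 14 Skipping	gene	fusion_skipping	lt65	20	196
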