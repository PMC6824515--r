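chr1	0	1400000	TAD_1	0	.
chr1	1400000	2500000	TAD_2	0	.
chr1	2500000	3300000	TAD_3	0	.
chr1	3300000	3800000	TAD_4	0	.
chr1	3800000	4000000	TAD_5	0	.
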