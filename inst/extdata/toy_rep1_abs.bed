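chr1	0	100000	0
chr1	100000	200000	1
chr1	200000	300000	2
chr1	300000	400000	3
chr1	400000	500000	4
chr1	500000	600000	5
chr1	600000	700000	6
chr1	700000	800000	7
chr1	800000	900000	8
chr1	900000	1000000	9
chr1	1000000	1100000	10
chr1	1100000	1200000	11
chr1	1200000	1300000	12
chr1	1300000	1400000	13
chr1	1400000	1500000	14
chr1	1500000	1600000	15
chr1	1600000	1700000	16
chr1	1700000	1800000	17
chr1	1800000	1900000	18
chr1	1900000	2000000	19
chr1	2000000	2100000	20
chr1	2100000	2200000	21
chr1	2200000	2300000	22
chr1	2300000	2400000	23
chr1	2400000	2500000	24
chr1	2500000	2600000	25
chr1	2600000	2700000	26
chr1	2700000	2800000	27
chr1	2800000	2900000	28
chr1	2900000	3000000	29
chr1	3000000	3100000	30
chr1	3100000	3200000	31
chr1	3200000	3300000	32
chr1	3300000	3400000	33
chr1	3400000	3500000	34
chr1	3500000	3600000	35
chr1	3600000	3700000	36
chr1	3700000	3800000	37
chr1	3800000	3900000	38
chr1	3900000	4000000	39
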