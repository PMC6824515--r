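0	0	1126
0	1	554
0	2	393
0	3	243
0	4	242
0	5	217
0	6	143
0	7	169
0	8	135
0	9	117
0	10	96
0	11	82
0	12	97
0	13	60
0	14	30
0	15	44
0	16	28
0	17	38
0	18	28
0	19	25
0	20	34
0	21	29
0	22	29
0	23	24
0	24	20
0	25	21
0	26	19
0	27	21
0	28	20
0	29	11
0	30	17
0	31	13
0	32	15
0	33	14
0	34	14
0	35	14
0	36	5
0	37	14
0	38	11
0	39	18
1	1	1132
1	2	561
1	3	362
1	4	262
1	5	217
1	6	179
1	7	155
1	8	133
1	9	113
1	10	125
1	11	101
1	12	105
1	13	79
1	14	45
1	15	46
1	16	31
1	17	34
1	18	35
1	19	37
1	20	19
1	21	24
1	22	19
1	23	26
1	24	28
1	25	23
1	26	30
1	27	26
1	28	17
1	29	14
1	30	19
1	31	30
1	32	21
1	33	13
1	34	20
1	35	14
1	36	16
1	37	12
1	38	11
1	39	19
2	2	1100
2	3	524
2	4	365
2	5	291
2	6	225
2	7	196
2	8	163
2	9	144
2	10	142
2	11	111
2	12	87
2	13	103
2	14	53
2	15	41
2	16	30
2	17	34
2	18	33
2	19	37
2	20	34
2	21	33
2	22	22
2	23	21
2	24	26
2	25	29
2	26	20
2	27	23
2	28	19
2	29	20
2	30	22
2	31	22
2	32	13
2	33	15
2	34	24
2	35	21
2	36	18
2	37	12
2	38	17
2	39	10
3	3	1047
3	4	555
3	5	385
3	6	287
3	7	235
3	8	195
3	9	145
3	10	143
3	11	130
3	12	125
3	13	94
3	14	44
3	15	54
3	16	27
3	17	35
3	18	32
3	19	28
3	20	31
3	21	30
3	22	33
3	23	26
3	24	24
3	25	21
3	26	18
3	27	29
3	28	12
3	29	15
3	30	22
3	31	21
3	32	8
3	33	18
3	34	15
3	35	17
3	36	16
3	37	17
3	38	17
3	39	18
4	4	1066
4	5	526
4	6	353
4	7	297
4	8	212
4	9	193
4	10	152
4	11	142
4	12	134
4	13	113
4	14	58
4	15	45
4	16	51
4	17	43
4	18	40
4	19	39
4	20	30
4	21	24
4	22	32
4	23	24
4	24	24
4	25	29
4	26	24
4	27	29
4	28	20
4	29	20
4	30	13
4	31	17
4	32	15
4	33	21
4	34	24
4	35	19
4	36	16
4	37	16
4	38	12
4	39	11
5	5	1063
5	6	567
5	7	396
5	8	256
5	9	228
5	10	197
5	11	142
5	12	154
5	13	122
5	14	54
5	15	49
5	16	50
5	17	41
5	18	41
5	19	39
5	20	34
5	21	28
5	22	30
5	23	29
5	24	26
5	25	28
5	26	32
5	27	15
5	28	24
5	29	19
5	30	20
5	31	17
5	32	18
5	33	16
5	34	27
5	35	19
5	36	15
5	37	16
5	38	16
5	39	17
6	6	1085
6	7	538
6	8	385
6	9	299
6	10	213
6	11	192
6	12	147
6	13	122
6	14	66
6	15	48
6	16	39
6	17	42
6	18	40
6	19	28
6	20	39
6	21	33
6	22	29
6	23	16
6	24	26
6	25	25
6	26	21
6	27	18
6	28	18
6	29	28
6	30	16
6	31	16
6	32	29
6	33	24
6	34	29
6	35	19
6	36	16
6	37	18
6	38	16
6	39	24
7	7	1077
7	8	549
7	9	396
7	10	272
7	11	207
7	12	168
7	13	162
7	14	70
7	15	60
7	16	51
7	17	37
7	18	40
7	19	36
7	20	46
7	21	34
7	22	28
7	23	36
7	24	32
7	25	23
7	26	26
7	27	27
7	28	25
7	29	17
7	30	30
7	31	23
7	32	20
7	33	7
7	34	17
7	35	22
7	36	21
7	37	17
7	38	16
7	39	19
8	8	1141
8	9	549
8	10	355
8	11	287
8	12	222
8	13	170
8	14	73
8	15	64
8	16	64
8	17	55
8	18	52
8	19	50
8	20	48
8	21	46
8	22	34
8	23	29
8	24	39
8	25	14
8	26	34
8	27	22
8	28	29
8	29	26
8	30	22
8	31	25
8	32	25
8	33	27
8	34	19
8	35	22
8	36	18
8	37	19
8	38	12
8	39	12
9	9	1163
9	10	543
9	11	401
9	12	263
9	13	232
9	14	80
9	15	63
9	16	76
9	17	60
9	18	48
9	19	54
9	20	49
9	21	48
9	22	47
9	23	37
9	24	27
9	25	27
9	26	42
9	27	31
9	28	22
9	29	28
9	30	34
9	31	22
9	32	26
9	33	20
9	34	20
9	35	15
9	36	27
9	37	25
9	38	15
9	39	16
10	10	1113
10	11	535
10	12	366
10	13	275
10	14	127
10	15	100
10	16	76
10	17	80
10	18	66
10	19	61
10	20	56
10	21	43
10	22	40
10	23	40
10	24	32
10	25	42
10	26	45
10	27	33
10	28	22
10	29	38
10	30	22
10	31	23
10	32	15
10	33	12
10	34	30
10	35	28
10	36	19
10	37	13
10	38	14
10	39	22
11	11	1045
11	12	510
11	13	355
11	14	139
11	15	118
11	16	89
11	17	80
11	18	50
11	19	57
11	20	41
11	21	42
11	22	30
11	23	61
11	24	36
11	25	39
11	26	34
11	27	26
11	28	30
11	29	27
11	30	23
11	31	22
11	32	28
11	33	27
11	34	14
11	35	21
11	36	18
11	37	14
11	38	23
11	39	12
12	12	1104
12	13	563
12	14	191
12	15	149
12	16	121
12	17	101
12	18	80
12	19	79
12	20	54
12	21	56
12	22	63
12	23	41
12	24	36
12	25	40
12	26	26
12	27	35
12	28	36
12	29	34
12	30	38
12	31	23
12	32	30
12	33	25
12	34	30
12	35	25
12	36	18
12	37	22
12	38	20
12	39	27
13	13	1099
13	14	268
13	15	152
13	16	141
13	17	105
13	18	71
13	19	75
13	20	59
13	21	66
13	22	46
13	23	56
13	24	50
13	25	39
13	26	32
13	27	36
13	28	24
13	29	35
13	30	44
13	31	32
13	32	38
13	33	23
13	34	27
13	35	26
13	36	12
13	37	22
13	38	14
13	39	13
14	14	1094
14	15	606
14	16	374
14	17	282
14	18	209
14	19	192
14	20	170
14	21	141
14	22	141
14	23	108
14	24	101
14	25	48
14	26	43
14	27	27
14	28	37
14	29	26
14	30	29
14	31	35
14	32	25
14	33	26
14	34	19
14	35	28
14	36	26
14	37	27
14	38	18
14	39	18
15	15	1146
15	16	563
15	17	392
15	18	262
15	19	245
15	20	170
15	21	185
15	22	141
15	23	116
15	24	112
15	25	53
15	26	47
15	27	39
15	28	40
15	29	30
15	30	27
15	31	36
15	32	33
15	33	33
15	34	37
15	35	29
15	36	23
15	37	21
15	38	40
15	39	15
16	16	1147
16	17	568
16	18	374
16	19	272
16	20	220
16	21	183
16	22	145
16	23	134
16	24	108
16	25	58
16	26	48
16	27	54
16	28	44
16	29	36
16	30	38
16	31	29
16	32	31
16	33	27
16	34	29
16	35	20
16	36	20
16	37	25
16	38	27
16	39	27
17	17	1125
17	18	566
17	19	380
17	20	296
17	21	213
17	22	194
17	23	147
17	24	140
17	25	55
17	26	55
17	27	50
17	28	58
17	29	44
17	30	48
17	31	32
17	32	31
17	33	30
17	34	29
17	35	32
17	36	27
17	37	22
17	38	35
17	39	31
18	18	1109
18	19	533
18	20	371
18	21	259
18	22	206
18	23	174
18	24	169
18	25	79
18	26	58
18	27	53
18	28	48
18	29	49
18	30	51
18	31	46
18	32	34
18	33	25
18	34	34
18	35	34
18	36	30
18	37	27
18	38	34
18	39	27
19	19	1063
19	20	570
19	21	387
19	22	283
19	23	227
19	24	175
19	25	86
19	26	70
19	27	77
19	28	58
19	29	52
19	30	49
19	31	38
19	32	32
19	33	38
19	34	31
19	35	31
19	36	27
19	37	25
19	38	30
19	39	29
20	20	1138
20	21	561
20	22	406
20	23	280
20	24	215
20	25	92
20	26	78
20	27	65
20	28	68
20	29	51
20	30	62
20	31	41
20	32	49
20	33	43
20	34	47
20	35	35
20	36	41
20	37	29
20	38	27
20	39	30
21	21	1080
21	22	550
21	23	362
21	24	273
21	25	96
21	26	84
21	27	62
21	28	69
21	29	52
21	30	52
21	31	50
21	32	47
21	33	40
21	34	34
21	35	41
21	36	37
21	37	40
21	38	30
21	39	29
22	22	1050
22	23	550
22	24	353
22	25	134
22	26	98
22	27	79
22	28	94
22	29	66
22	30	63
22	31	48
22	32	47
22	33	48
22	34	42
22	35	34
22	36	40
22	37	45
22	38	34
22	39	37
23	23	1142
23	24	550
23	25	173
23	26	152
23	27	123
23	28	98
23	29	61
23	30	60
23	31	62
23	32	64
23	33	53
23	34	41
23	35	37
23	36	42
23	37	38
23	38	33
23	39	31
24	24	1135
24	25	265
24	26	173
24	27	133
24	28	131
24	29	105
24	30	76
24	31	61
24	32	76
24	33	53
24	34	54
24	35	40
24	36	50
24	37	41
24	38	31
24	39	44
25	25	1119
25	26	585
25	27	395
25	28	287
25	29	243
25	30	186
25	31	145
25	32	157
25	33	65
25	34	62
25	35	41
25	36	59
25	37	46
25	38	39
25	39	26
26	26	1118
26	27	535
26	28	370
26	29	251
26	30	235
26	31	181
26	32	170
26	33	72
26	34	84
26	35	53
26	36	57
26	37	27
26	38	51
26	39	33
27	27	1123
27	28	549
27	29	351
27	30	279
27	31	180
27	32	190
27	33	67
27	34	78
27	35	72
27	36	55
27	37	52
27	38	56
27	39	37
28	28	1144
28	29	544
28	30	416
28	31	286
28	32	210
28	33	104
28	34	86
28	35	68
28	36	55
28	37	56
28	38	57
28	39	45
29	29	1068
29	30	527
29	31	363
29	32	266
29	33	99
29	34	94
29	35	75
29	36	68
29	37	62
29	38	57
29	39	56
30	30	1094
30	31	545
30	32	378
30	33	150
30	34	122
30	35	88
30	36	69
30	37	66
30	38	87
30	39	60
31	31	1124
31	32	536
31	33	192
31	34	123
31	35	122
31	36	78
31	37	76
31	38	76
31	39	60
32	32	1093
32	33	262
32	34	175
32	35	130
32	36	120
32	37	88
32	38	75
32	39	53
33	33	1070
33	34	542
33	35	367
33	36	255
33	37	212
33	38	86
33	39	75
34	34	1155
34	35	534
34	36	365
34	37	269
34	38	121
34	39	112
35	35	1152
35	36	572
35	37	360
35	38	131
35	39	105
36	36	1076
36	37	553
36	38	206
36	39	145
37	37	1124
37	38	274
37	39	159
38	38	1123
38	39	522
39	39	1105
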