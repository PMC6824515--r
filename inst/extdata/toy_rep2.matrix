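0	0	1123
0	1	527
0	2	355
0	3	270
0	4	205
0	5	182
0	6	158
0	7	151
0	8	139
0	9	122
0	10	102
0	11	100
0	12	96
0	13	78
0	14	35
0	15	33
0	16	38
0	17	32
0	18	38
0	19	24
0	20	25
0	21	17
0	22	12
0	23	29
0	24	18
0	25	19
0	26	23
0	27	21
0	28	20
0	29	23
0	30	16
0	31	16
0	32	17
0	33	13
0	34	11
0	35	12
0	36	16
0	37	20
0	38	10
0	39	11
1	1	1041
1	2	564
1	3	359
1	4	298
1	5	218
1	6	193
1	7	165
1	8	129
1	9	117
1	10	116
1	11	100
1	12	87
1	13	90
1	14	42
1	15	36
1	16	35
1	17	28
1	18	25
1	19	27
1	20	24
1	21	27
1	22	23
1	23	36
1	24	26
1	25	23
1	26	22
1	27	25
1	28	18
1	29	17
1	30	14
1	31	11
1	32	13
1	33	14
1	34	14
1	35	19
1	36	13
1	37	11
1	38	18
1	39	13
2	2	1140
2	3	543
2	4	380
2	5	246
2	6	246
2	7	172
2	8	166
2	9	139
2	10	122
2	11	102
2	12	107
2	13	78
2	14	41
2	15	36
2	16	38
2	17	42
2	18	31
2	19	28
2	20	26
2	21	18
2	22	32
2	23	20
2	24	16
2	25	21
2	26	22
2	27	25
2	28	26
2	29	23
2	30	19
2	31	19
2	32	23
2	33	22
2	34	15
2	35	20
2	36	19
2	37	16
2	38	12
2	39	16
3	3	1098
3	4	558
3	5	369
3	6	267
3	7	222
3	8	178
3	9	145
3	10	154
3	11	140
3	12	130
3	13	119
3	14	38
3	15	45
3	16	40
3	17	37
3	18	31
3	19	34
3	20	44
3	21	24
3	22	34
3	23	32
3	24	27
3	25	21
3	26	21
3	27	25
3	28	21
3	29	23
3	30	22
3	31	16
3	32	19
3	33	14
3	34	18
3	35	12
3	36	23
3	37	13
3	38	14
3	39	11
4	4	1079
4	5	598
4	6	366
4	7	297
4	8	216
4	9	169
4	10	147
4	11	139
4	12	125
4	13	133
4	14	51
4	15	50
4	16	34
4	17	42
4	18	34
4	19	46
4	20	37
4	21	23
4	22	41
4	23	24
4	24	27
4	25	19
4	26	22
4	27	28
4	28	21
4	29	26
4	30	23
4	31	20
4	32	29
4	33	23
4	34	19
4	35	16
4	36	12
4	37	10
4	38	18
4	39	12
5	5	1163
5	6	560
5	7	400
5	8	257
5	9	218
5	10	203
5	11	150
5	12	125
5	13	125
5	14	59
5	15	58
5	16	42
5	17	37
5	18	37
5	19	38
5	20	38
5	21	31
5	22	32
5	23	23
5	24	29
5	25	33
5	26	26
5	27	25
5	28	23
5	29	25
5	30	19
5	31	24
5	32	14
5	33	17
5	34	21
5	35	13
5	36	16
5	37	20
5	38	20
5	39	17
6	6	1112
6	7	594
6	8	342
6	9	275
6	10	228
6	11	177
6	12	176
6	13	148
6	14	46
6	15	50
6	16	46
6	17	57
6	18	49
6	19	40
6	20	33
6	21	41
6	22	33
6	23	34
6	24	21
6	25	32
6	26	23
6	27	30
6	28	20
6	29	23
6	30	31
6	31	18
6	32	21
6	33	18
6	34	17
6	35	13
6	36	16
6	37	10
6	38	14
6	39	15
7	7	1173
7	8	563
7	9	364
7	10	244
7	11	205
7	12	168
7	13	136
7	14	70
7	15	69
7	16	41
7	17	47
7	18	53
7	19	50
7	20	33
7	21	32
7	22	37
7	23	38
7	24	36
7	25	34
7	26	16
7	27	31
7	28	29
7	29	17
7	30	25
7	31	17
7	32	17
7	33	17
7	34	18
7	35	14
7	36	22
7	37	21
7	38	18
7	39	21
8	8	1084
8	9	510
8	10	397
8	11	272
8	12	215
8	13	179
8	14	86
8	15	67
8	16	71
8	17	58
8	18	65
8	19	51
8	20	32
8	21	28
8	22	36
8	23	34
8	24	26
8	25	33
8	26	24
8	27	35
8	28	21
8	29	21
8	30	21
8	31	25
8	32	17
8	33	21
8	34	22
8	35	28
8	36	17
8	37	21
8	38	19
8	39	18
9	9	1018
9	10	525
9	11	395
9	12	256
9	13	218
9	14	79
9	15	81
9	16	55
9	17	67
9	18	55
9	19	50
9	20	52
9	21	42
9	22	48
9	23	40
9	24	26
9	25	37
9	26	21
9	27	34
9	28	36
9	29	22
9	30	26
9	31	30
9	32	26
9	33	23
9	34	17
9	35	25
9	36	17
9	37	25
9	38	18
9	39	20
10	10	1102
10	11	541
10	12	390
10	13	298
10	14	118
10	15	90
10	16	72
10	17	52
10	18	73
10	19	55
10	20	45
10	21	54
10	22	42
10	23	46
10	24	28
10	25	26
10	26	29
10	27	27
10	28	25
10	29	30
10	30	23
10	31	24
10	32	19
10	33	26
10	34	18
10	35	20
10	36	22
10	37	19
10	38	25
10	39	12
11	11	1118
11	12	526
11	13	375
11	14	152
11	15	101
11	16	82
11	17	83
11	18	70
11	19	62
11	20	60
11	21	47
11	22	43
11	23	37
11	24	40
11	25	39
11	26	37
11	27	37
11	28	33
11	29	27
11	30	21
11	31	28
11	32	21
11	33	13
11	34	17
11	35	15
11	36	18
11	37	21
11	38	11
11	39	26
12	12	1099
12	13	558
12	14	199
12	15	142
12	16	121
12	17	89
12	18	61
12	19	60
12	20	69
12	21	44
12	22	57
12	23	45
12	24	44
12	25	33
12	26	33
12	27	35
12	28	33
12	29	26
12	30	24
12	31	30
12	32	28
12	33	17
12	34	35
12	35	18
12	36	14
12	37	24
12	38	25
12	39	28
13	13	1084
13	14	282
13	15	193
13	16	140
13	17	109
13	18	86
13	19	90
13	20	63
13	21	60
13	22	53
13	23	53
13	24	37
13	25	55
13	26	36
13	27	45
13	28	35
13	29	34
13	30	31
13	31	26
13	32	33
13	33	27
13	34	25
13	35	33
13	36	23
13	37	18
13	38	18
13	39	22
14	14	1106
14	15	565
14	16	380
14	17	287
14	18	219
14	19	203
14	20	165
14	21	136
14	22	123
14	23	109
14	24	111
14	25	40
14	26	35
14	27	31
14	28	32
14	29	48
14	30	23
14	31	42
14	32	24
14	33	28
14	34	18
14	35	27
14	36	27
14	37	19
14	38	22
14	39	20
15	15	1142
15	16	587
15	17	368
15	18	288
15	19	228
15	20	196
15	21	164
15	22	162
15	23	129
15	24	101
15	25	49
15	26	42
15	27	38
15	28	36
15	29	38
15	30	36
15	31	23
15	32	27
15	33	38
15	34	27
15	35	18
15	36	25
15	37	19
15	38	18
15	39	18
16	16	1128
16	17	563
16	18	364
16	19	261
16	20	228
16	21	171
16	22	153
16	23	124
16	24	129
16	25	63
16	26	52
16	27	53
16	28	42
16	29	39
16	30	31
16	31	35
16	32	28
16	33	30
16	34	28
16	35	23
16	36	25
16	37	26
16	38	30
16	39	17
17	17	1080
17	18	508
17	19	366
17	20	263
17	21	208
17	22	172
17	23	145
17	24	138
17	25	69
17	26	43
17	27	49
17	28	39
17	29	32
17	30	41
17	31	28
17	32	37
17	33	33
17	34	22
17	35	23
17	36	26
17	37	28
17	38	30
17	39	18
18	18	1118
18	19	558
18	20	394
18	21	277
18	22	241
18	23	190
18	24	148
18	25	72
18	26	63
18	27	48
18	28	45
18	29	53
18	30	34
18	31	43
18	32	28
18	33	33
18	34	25
18	35	26
18	36	27
18	37	27
18	38	23
18	39	20
19	19	1107
19	20	541
19	21	375
19	22	289
19	23	220
19	24	190
19	25	77
19	26	63
19	27	59
19	28	52
19	29	43
19	30	37
19	31	41
19	32	33
19	33	51
19	34	39
19	35	38
19	36	38
19	37	40
19	38	27
19	39	18
20	20	1151
20	21	559
20	22	386
20	23	279
20	24	237
20	25	101
20	26	79
20	27	77
20	28	64
20	29	56
20	30	50
20	31	50
20	32	45
20	33	35
20	34	40
20	35	36
20	36	32
20	37	36
20	38	21
20	39	23
21	21	1114
21	22	552
21	23	388
21	24	245
21	25	112
21	26	107
21	27	86
21	28	63
21	29	63
21	30	51
21	31	43
21	32	59
21	33	49
21	34	40
21	35	37
21	36	29
21	37	38
21	38	30
21	39	22
22	22	1131
22	23	534
22	24	375
22	25	155
22	26	118
22	27	106
22	28	87
22	29	73
22	30	61
22	31	59
22	32	45
22	33	54
22	34	39
22	35	49
22	36	24
22	37	23
22	38	40
22	39	29
23	23	1136
23	24	547
23	25	166
23	26	145
23	27	106
23	28	86
23	29	67
23	30	73
23	31	54
23	32	47
23	33	45
23	34	50
23	35	39
23	36	42
23	37	38
23	38	40
23	39	33
24	24	1069
24	25	256
24	26	198
24	27	143
24	28	125
24	29	93
24	30	74
24	31	72
24	32	62
24	33	59
24	34	67
24	35	45
24	36	40
24	37	36
24	38	42
24	39	44
25	25	1083
25	26	561
25	27	341
25	28	283
25	29	223
25	30	187
25	31	160
25	32	144
25	33	69
25	34	58
25	35	51
25	36	62
25	37	36
25	38	47
25	39	32
26	26	1210
26	27	563
26	28	417
26	29	311
26	30	217
26	31	195
26	32	138
26	33	54
26	34	61
26	35	50
26	36	49
26	37	52
26	38	42
26	39	29
27	27	1088
27	28	540
27	29	355
27	30	259
27	31	236
27	32	176
27	33	90
27	34	69
27	35	49
27	36	71
27	37	55
27	38	54
27	39	57
28	28	1123
28	29	569
28	30	357
28	31	273
28	32	227
28	33	68
28	34	65
28	35	59
28	36	63
28	37	55
28	38	44
28	39	58
29	29	1136
29	30	534
29	31	353
29	32	282
29	33	109
29	34	99
29	35	65
29	36	67
29	37	68
29	38	50
29	39	56
30	30	1090
30	31	544
30	32	355
30	33	136
30	34	125
30	35	102
30	36	83
30	37	56
30	38	62
30	39	65
31	31	1114
31	32	507
31	33	176
31	34	122
31	35	113
31	36	97
31	37	93
31	38	76
31	39	58
32	32	1129
32	33	304
32	34	184
32	35	147
32	36	96
32	37	89
32	38	86
32	39	71
33	33	1126
33	34	539
33	35	379
33	36	304
33	37	225
33	38	88
33	39	88
34	34	1159
34	35	554
34	36	368
34	37	306
34	38	112
34	39	89
35	35	1072
35	36	573
35	37	360
35	38	136
35	39	105
36	36	1122
36	37	579
36	38	182
36	39	149
37	37	1123
37	38	262
37	39	168
38	38	1055
38	39	527
39	39	1085
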