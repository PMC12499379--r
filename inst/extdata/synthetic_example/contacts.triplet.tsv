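0	0	145
0	1	107
1	1	129
0	2	75
1	2	119
2	2	112
0	3	39
1	3	61
2	3	144
3	3	124
0	4	45
1	4	54
2	4	62
3	4	141
4	4	125
0	5	19
1	5	35
2	5	45
3	5	59
4	5	117
5	5	135
0	6	13
1	6	33
2	6	33
3	6	42
4	6	58
5	6	117
6	6	120
0	7	19
1	7	22
2	7	24
3	7	30
4	7	42
5	7	63
6	7	122
7	7	119
0	8	22
1	8	25
2	8	27
3	8	20
4	8	30
5	8	55
6	8	61
7	8	131
8	8	117
0	9	7
1	9	12
2	9	20
3	9	17
4	9	15
5	9	8
6	9	19
7	9	31
8	9	61
9	9	120
0	10	7
1	10	17
2	10	25
3	10	21
4	10	19
5	10	15
6	10	18
7	10	23
8	10	30
9	10	125
10	10	110
0	11	11
1	11	14
2	11	36
3	11	28
4	11	11
5	11	10
6	11	19
7	11	14
8	11	18
9	11	60
10	11	116
11	11	118
0	12	6
1	12	15
2	12	21
3	12	16
4	12	18
5	12	7
6	12	7
7	12	15
8	12	15
9	12	31
10	12	55
11	12	126
12	12	119
0	13	9
1	13	8
2	13	10
3	13	14
4	13	8
5	13	7
6	13	11
7	13	6
8	13	26
9	13	35
10	13	45
11	13	61
12	13	116
13	13	127
0	14	4
1	14	10
2	14	8
3	14	14
4	14	13
5	14	4
6	14	6
7	14	11
8	14	8
9	14	28
10	14	31
11	14	30
12	14	65
13	14	119
14	14	126
0	15	4
1	15	15
2	15	16
3	15	12
4	15	4
5	15	7
6	15	9
7	15	6
8	15	6
9	15	16
10	15	28
11	15	32
12	15	47
13	15	54
14	15	117
15	15	123
0	16	9
1	16	10
2	16	21
3	16	13
4	16	4
5	16	6
6	16	3
7	16	7
8	16	5
9	16	16
10	16	16
11	16	27
12	16	21
13	16	38
14	16	57
15	16	118
16	16	122
0	17	7
1	17	4
2	17	15
3	17	12
4	17	6
5	17	5
6	17	7
7	17	6
8	17	11
9	17	15
10	17	17
11	17	23
12	17	29
13	17	28
14	17	42
15	17	58
16	17	149
17	17	120
0	18	3
1	18	7
2	18	7
3	18	6
4	18	4
5	18	6
6	18	1
7	18	8
8	18	4
9	18	13
10	18	12
11	18	23
12	18	20
13	18	27
14	18	29
15	18	32
16	18	68
17	18	125
18	18	100
0	19	2
2	19	4
3	19	5
4	19	5
5	19	2
6	19	2
7	19	1
8	19	3
9	19	8
10	19	14
11	19	12
12	19	9
13	19	11
14	19	20
15	19	31
16	19	34
17	19	44
18	19	95
19	19	134
0	20	2
1	20	7
2	20	4
3	20	10
4	20	6
5	20	3
6	20	3
7	20	6
8	20	11
9	20	5
10	20	4
11	20	6
12	20	2
13	20	8
14	20	5
15	20	12
16	20	8
17	20	10
18	20	16
19	20	55
20	20	109
0	21	2
1	21	4
2	21	1
3	21	2
4	21	5
5	21	8
6	21	4
7	21	7
8	21	7
9	21	2
10	21	1
11	21	7
12	21	2
13	21	5
14	21	4
15	21	5
16	21	7
17	21	8
18	21	6
19	21	34
20	21	118
21	21	117
0	22	6
1	22	1
2	22	3
3	22	5
4	22	5
5	22	5
6	22	3
7	22	6
8	22	6
9	22	2
10	22	1
11	22	3
12	22	4
13	22	5
14	22	3
15	22	3
16	22	5
17	22	13
18	22	13
19	22	26
20	22	55
21	22	119
22	22	100
0	23	3
1	23	1
2	23	4
4	23	3
5	23	2
6	23	6
7	23	5
8	23	6
9	23	2
10	23	1
11	23	2
12	23	7
13	23	3
14	23	12
15	23	9
16	23	3
17	23	6
18	23	6
19	23	14
20	23	35
21	23	55
22	23	132
23	23	130
0	24	4
1	24	3
2	24	3
3	24	6
4	24	4
5	24	6
6	24	3
7	24	6
8	24	9
9	24	3
10	24	4
11	24	2
12	24	4
13	24	3
14	24	3
15	24	6
16	24	3
17	24	3
18	24	7
19	24	11
20	24	28
21	24	44
22	24	71
23	24	134
24	24	144
0	25	5
1	25	5
2	25	1
3	25	2
4	25	3
5	25	6
6	25	5
7	25	5
8	25	4
9	25	4
10	25	3
11	25	4
12	25	4
13	25	3
14	25	3
15	25	3
16	25	6
17	25	8
18	25	4
19	25	9
20	25	32
21	25	24
22	25	41
23	25	63
24	25	122
25	25	120
0	26	6
2	26	6
3	26	3
4	26	4
5	26	5
6	26	2
7	26	4
8	26	7
9	26	2
10	26	3
11	26	2
12	26	3
13	26	2
14	26	9
15	26	2
16	26	3
17	26	8
18	26	8
19	26	7
20	26	19
21	26	23
22	26	22
23	26	48
24	26	74
25	26	91
26	26	93
0	27	4
1	27	3
2	27	1
3	27	4
4	27	3
5	27	6
6	27	1
7	27	8
8	27	2
10	27	1
11	27	5
12	27	7
13	27	3
14	27	3
15	27	1
16	27	5
17	27	4
18	27	3
19	27	13
20	27	17
21	27	17
22	27	21
23	27	33
24	27	38
25	27	69
26	27	125
27	27	112
0	28	1
1	28	5
2	28	5
3	28	4
4	28	4
5	28	6
6	28	6
7	28	2
8	28	3
10	28	1
11	28	6
13	28	3
15	28	4
16	28	2
17	28	4
18	28	6
19	28	8
20	28	19
21	28	17
22	28	20
23	28	26
24	28	32
25	28	39
26	28	49
27	28	122
28	28	140
0	29	1
1	29	2
2	29	4
4	29	3
5	29	2
6	29	4
7	29	9
8	29	4
9	29	2
10	29	5
13	29	2
14	29	3
15	29	3
16	29	5
17	29	5
18	29	3
19	29	4
20	29	9
21	29	17
22	29	26
23	29	24
24	29	16
25	29	28
26	29	38
27	29	53
28	29	126
29	29	123
0	30	5
1	30	6
2	30	1
3	30	4
4	30	1
5	30	8
6	30	9
7	30	3
8	30	5
9	30	5
10	30	3
12	30	2
13	30	2
14	30	3
15	30	3
17	30	4
18	30	5
19	30	7
20	30	8
21	30	7
22	30	15
23	30	13
24	30	27
25	30	25
26	30	33
27	30	40
28	30	64
29	30	123
30	30	115
0	31	3
1	31	2
2	31	1
4	31	3
5	31	1
6	31	4
7	31	2
8	31	3
9	31	1
10	31	5
11	31	3
12	31	8
13	31	12
14	31	5
15	31	5
16	31	3
17	31	5
18	31	6
19	31	8
20	31	5
21	31	7
22	31	5
23	31	7
24	31	10
25	31	9
26	31	10
27	31	8
28	31	19
29	31	26
30	31	47
31	31	123
0	32	1
1	32	1
3	32	3
4	32	2
6	32	1
7	32	3
8	32	2
9	32	4
10	32	2
11	32	3
12	32	5
13	32	4
14	32	5
15	32	8
16	32	6
17	32	7
18	32	8
19	32	8
20	32	3
21	32	5
22	32	9
23	32	7
24	32	6
25	32	10
26	32	8
27	32	5
28	32	7
29	32	24
30	32	19
31	32	119
32	32	121
0	33	1
1	33	1
2	33	2
3	33	2
4	33	2
6	33	2
9	33	2
10	33	2
11	33	3
12	33	1
13	33	3
14	33	8
15	33	2
16	33	5
17	33	11
18	33	7
19	33	6
20	33	4
21	33	4
22	33	7
23	33	8
24	33	12
25	33	4
26	33	3
27	33	6
28	33	12
29	33	19
30	33	13
31	33	60
32	33	119
33	33	124
0	34	2
1	34	1
2	34	1
6	34	1
7	34	3
8	34	1
9	34	2
10	34	6
11	34	2
12	34	3
13	34	9
14	34	4
15	34	5
16	34	4
17	34	5
18	34	5
19	34	7
20	34	1
21	34	3
22	34	9
23	34	6
24	34	6
25	34	3
26	34	8
27	34	9
28	34	14
29	34	14
30	34	22
31	34	39
32	34	61
33	34	117
34	34	107
1	35	2
2	35	1
3	35	1
5	35	1
6	35	3
7	35	3
8	35	3
9	35	3
10	35	3
11	35	7
12	35	3
13	35	3
14	35	7
15	35	2
16	35	2
17	35	9
18	35	3
19	35	4
20	35	7
21	35	6
22	35	6
23	35	8
24	35	4
25	35	7
26	35	5
27	35	9
28	35	6
29	35	15
30	35	8
31	35	25
32	35	46
33	35	52
34	35	136
35	35	127
4	36	1
6	36	3
7	36	2
8	36	2
9	36	2
11	36	3
12	36	5
13	36	4
14	36	6
15	36	3
16	36	4
17	36	3
18	36	3
19	36	9
21	36	4
22	36	4
23	36	7
24	36	1
25	36	3
26	36	7
27	36	3
28	36	7
29	36	6
30	36	7
31	36	35
32	36	25
33	36	40
34	36	70
35	36	121
36	36	119
1	37	2
6	37	1
7	37	1
8	37	1
9	37	3
10	37	2
11	37	3
12	37	7
13	37	5
14	37	7
15	37	3
16	37	6
17	37	6
18	37	4
19	37	8
20	37	2
21	37	6
22	37	2
23	37	3
24	37	3
25	37	4
26	37	2
27	37	13
28	37	6
29	37	10
30	37	12
31	37	17
32	37	24
33	37	29
34	37	35
35	37	52
36	37	134
37	37	132
0	38	1
2	38	1
3	38	4
4	38	5
5	38	2
7	38	4
8	38	2
9	38	4
10	38	3
11	38	3
12	38	1
13	38	3
14	38	2
15	38	4
16	38	3
17	38	2
18	38	4
19	38	6
20	38	6
21	38	1
22	38	4
23	38	2
24	38	8
25	38	1
26	38	9
27	38	6
28	38	4
29	38	7
30	38	6
31	38	21
32	38	14
33	38	27
34	38	30
35	38	42
36	38	56
37	38	92
38	38	127
0	39	3
2	39	1
3	39	1
4	39	3
5	39	1
7	39	2
8	39	1
9	39	1
11	39	2
12	39	8
13	39	3
14	39	5
15	39	3
16	39	5
17	39	3
18	39	3
19	39	9
20	39	3
21	39	3
22	39	7
23	39	2
24	39	5
25	39	6
26	39	4
27	39	2
28	39	3
29	39	6
30	39	3
31	39	19
32	39	16
33	39	26
34	39	13
35	39	30
36	39	44
37	39	59
38	39	126
39	39	121
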