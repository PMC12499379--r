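bin	label
0	A
1	A
2	A
3	A
4	A
5	A
6	A
7	A
8	A
9	B
10	B
11	B
12	B
13	B
14	B
15	B
16	B
17	B
18	B
19	B
20	A
21	A
22	A
23	A
24	A
25	A
26	A
27	A
28	A
29	A
30	A
31	B
32	B
33	B
34	B
35	B
36	B
37	B
38	B
39	B
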