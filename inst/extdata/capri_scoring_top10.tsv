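target	method	rmsd_filtered	N	R
T22	GA	yes	3	4
T23	GA	yes	10	1
T25	GA	yes	1	5
T26	GA	yes	2	6
T27	GA	yes	3	6
T29	GA	yes	2	5
T32	GA	yes	2	3
T35	GA	yes	0	NA
T37	GA	yes	1	1
T39	GA	yes	0	107
T40A	GA	yes	2	2
T40B	GA	yes	0	13
T22	CF	yes	2	3
T23	CF	yes	9	1
T25	CF	yes	2	2
T26	CF	yes	5	1
T27	CF	yes	5	1
T29	CF	yes	4	1
T32	CF	yes	2	3
T35	CF	yes	1	2
T37	CF	yes	1	5
T39	CF	yes	0	48
T40A	CF	yes	2	1
T40B	CF	yes	0	13
T22	CF-GA	yes	2	4
T23	CF-GA	yes	9	1
T25	CF-GA	yes	2	2
T26	CF-GA	yes	5	1
T27	CF-GA	yes	4	1
T29	CF-GA	yes	2	2
T32	CF-GA	yes	3	10
T35	CF-GA	yes	1	1
T37	CF-GA	yes	1	3
T39	CF-GA	yes	0	99
T40A	CF-GA	yes	3	1
T40B	CF-GA	yes	0	16
T22	CF-GA	no	2	4
T23	CF-GA	no	10	1
T25	CF-GA	no	4	2
T26	CF-GA	no	6	1
T27	CF-GA	no	5	1
T29	CF-GA	no	6	2
T32	CF-GA	no	2	6
T35	CF-GA	no	1	1
T37	CF-GA	no	1	3
T39	CF-GA	no	0	205
T40A	CF-GA	no	4	1
T40B	CF-GA	no	0	48
T22	CF-then-GA	no	2	4
T23	CF-then-GA	no	10	1
T25	CF-then-GA	no	4	2
T26	CF-then-GA	no	7	1
T27	CF-then-GA	no	6	1
T29	CF-then-GA	no	6	2
T32	CF-then-GA	no	0	16
T35	CF-then-GA	no	0	NA
T37	CF-then-GA	no	0	16
T39	CF-then-GA	no	0	NA
T40A	CF-then-GA	no	5	1
T40B	CF-then-GA	no	0	40
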