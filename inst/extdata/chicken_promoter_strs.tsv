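# str_per_seq=0.114
motif	count	freq_percent
AC	405	25.9
AT	276	17.6
AG	174	11.1
AGG	131	8.4
AAT	68	4.3
CCG	66	4.2
AAC	46	2.9
AGC	40	2.6
AAAT	30	1.9
AAAG	26	1.7
CG	26	1.7
ATCCC	18	1.2
AAAC	17	1.1
AAGG	15	1.0
AAG	13	0.8
ACC	13	0.8
AGAGG	13	0.8
ATCC	12	0.8
ACGGC	12	0.8
AAGGG	11	0.7
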