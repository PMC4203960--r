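# str_per_seq=0.101
motif	count	freq_percent
AC	433	31.5
AT	294	21.4
AG	174	12.7
AGG	98	7.1
AAT	61	4.4
CCG	1	0.1
AAC	38	2.8
AGC	26	1.9
AAAT	49	3.6
AAAG	21	1.5
CG	0	0.0
ATCCC	6	0.4
AAAC	33	2.4
AAGG	11	0.8
AAG	9	0.7
ACC	8	0.6
AGAGG	5	0.4
ATCC	5	0.4
ACGGC	0	0.0
AAGGG	22	1.6
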