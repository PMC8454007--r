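ref	pos	ref_base	depth	A	C	G	T
sp01	1	A	12	12	0	0	0
sp01	2	C	11	0	10	1	0
sp01	3	G	13	0	0	13	0
sp01	4	T	9	1	0	0	8
sp01	5	A	10	10	0	0	0
sp01	6	A	3	3	0	0	0
sp01	7	C	8	0	8	0	0
sp01	8	G	15	0	1	14	0
sp01	9	T	12	0	0	0	12
sp01	10	A	11	11	0	0	0
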