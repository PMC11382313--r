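accession	gene	predicted_span	neo_position	uniprot_experimental	uniprot_span	topfind
O00115	DNASE2	1-16	17	No	1-18	-
P13667	PDIA4	1-24	25	No	1-20	+
P04843	RPN1	1-24	25	No	1-23	+
Q14257	RCN2	1-25	26	No	1-22	+
Q9Y3Q3	TMED3	1-27	28	No	1-23	+
O95302	FKBP9	1-29	30	No	1-24	-
P11047	LAMC1	1-35	36	No	1-33	-
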