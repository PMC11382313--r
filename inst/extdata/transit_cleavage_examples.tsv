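accession	gene	predicted_span	neo_position	uniprot_experimental	uniprot_span	topfind
P82673	MRPS35	1-22	23	No	1-?	+
Q8TD30	GPT2	1-24	25	No	-	+
Q9Y2Q9	MRPS28	1-28	29	No	1-71	+
P49419	ALDH7A1	1-29	30	No	1-26	-
Q9BX68	HINT2	1-30	31	No	1-17	+
P49590	HARS2	1-34	35	No	1-33	+
P54886	ALDH18A1	1-43	44	No	-	+
Q7Z6M4	MTERF4	1-43	44	Yes	1-42	-
P06576	ATP5F1B	1-46	47	Yes	1-47	+
P82650	MRPS22	1-53	54	No	-	+
Q9H2K0	MTIF3	1-55	56	No	1-31	+
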