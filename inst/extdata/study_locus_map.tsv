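locus	chromosome	cyto_order	inside_of	region
dsub11	A	1	A_1	I
dsub37	A	2	A_1	I
dsub76	A	3	A_2	II
dsub05	A	4	A_2	II
dsub21	A	5	A_2	II
dsub39	A	6	A_2	II
dsub70	A	7		III
dsub19	A	8		III
dsub18	J	1		NA
dsub59	J	2	J_1	NA
dsub69	J	3	J_1	NA
dsub74	J	4		NA
dsub62	J	5		NA
dsub27	J	6		NA
dsub10	U	1		NA
dsub03	U	2		NA
dsub42	U	3	U_1+2,U_1+2+8	NA
dsub64	U	4	U_1+2,U_1+2+8	NA
dsub15	U	5		NA
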