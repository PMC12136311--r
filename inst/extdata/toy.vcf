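##fileformat=VCFv4.2
##source=m3vcf toy example (synthetic)
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S001	S002	S003
22	16050075	rs1	A	G	.	PASS	.	GT:DS	0|0:0.0	0|1:1.0	1|1:2.0
22	16050115	rs2	G	A	.	PASS	.	GT:DS	0|0:0.0	0|0:0.1	0|1:1.0
22	16050213	rs3	C	T	.	PASS	.	GT:DS	1|1:2.0	1|0:1.0	1|1:1.9
22	16050319	rs4	T	C	.	PASS	.	GT:DS	0|0:0.0	0|1:1.0	0|0:0.2
22	16050527	rs5	C	A	.	PASS	.	GT:DS	0|1:1.0	0|1:0.9	1|1:2.0
22	16050654	rs6	A	C	.	PASS	.	GT:DS	1|0:1.0	0|0:0.0	0|1:1.1
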