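##fileformat=VCFv4.2
##INFO=<ID=SVTYPE,Number=1,Type=String,Description="Structural variant type">
##INFO=<ID=END,Number=1,Type=Integer,Description="End position">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	child	father	mother
1	101230	.	A	T	.	PASS	.	GT:GQ	0/1:99	0/1:87	0/0:95
1	240360	.	G	C	.	PASS	.	GT:GQ	1/1:80	0/1:77	0/1:91
2	55120	.	CT	C	.	PASS	.	GT:GQ	0/1:64	0/0:88	0/1:15
3	1000000	.	N	<DEL>	.	PASS	SVTYPE=DEL;END=1040000	GT:GQ	0/1:72	0/0:90	0/1:66
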