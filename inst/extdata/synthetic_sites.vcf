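##fileformat=VCFv4.2
##contig=<ID=1,length=1000000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DS,Number=1,Type=Float,Description="Imputed dosage">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3	S4
1	100	rs1	A	G	.	PASS	.	GT:DS	0/1:1.1	1|1:1.9	0/0:0.1	./.:0.5
1	200	rs2	C	T	.	PASS	.	GT:DS	0/0:0.0	0/1:0.9	1/1:2.0	0|1:1.46
1	300	rs3	G	A,T	.	PASS	.	GT:DS	0/1:1.0	0/2:1.5	1/1:2.0	0/0:0.0
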