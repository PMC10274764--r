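##fileformat=VCFv4.2
##contig=<ID=chr1,length=100000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2	S3
chr1	1000	.	A	G	.	PASS	.	GT	0|1	1|1	0|0
chr1	2000	.	C	T	.	PASS	.	GT	0|0	0|1	1|0
chr1	3500	.	G	A	.	PASS	.	GT	1|1	0|0	0|1
chr1	5000	.	T	C	.	PASS	.	GT	0|1	0|1	0|1
chr1	6200	.	A	C	.	PASS	.	GT	1|0	1|0	0|0
chr1	7800	.	G	T	.	PASS	.	GT	0|0	1|1	1|1
chr1	9000	.	C	G	.	PASS	.	GT	0|1	1|0	0|0
chr1	12000	.	A	T	.	PASS	.	GT	1|1	1|1	0|0
chr1	15000	.	T	G	.	PASS	.	GT	0|0	0|0	1|1
chr1	20000	.	C	A	.	PASS	.	GT	0|1	0|0	1|1
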