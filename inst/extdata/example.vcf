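##fileformat=VCFv4.2
##source=synthetic example, hand-written for reader tests
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	cow01	cow02	cow03
1	1000	rs1	A	G	50	PASS	.	GT	0/0	0/1	1/1
1	2000	rs2	C	T	50	PASS	.	GT:DP	1|1:10	0|1:12	0|0:9
1	3500	rs3	G	A	50	PASS	.	GT	./.	0/1	0/0
2	500	rs4	T	C	50	PASS	.	GT	0/1	1/1	0/1
2	900	.	A	C	50	PASS	.	GT	0/0	0/0	0/1
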