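##fileformat=VCFv4.2
##contig=<ID=8>
##INFO=<ID=NS,Number=1,Type=Integer,Description="Number of samples">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S001	S002	S003
8	18400285	rs1801280	T	C	.	PASS	NS=3	GT	0/0	0/0	0|0
8	18400484	rs1799930	G	A	.	PASS	NS=3	GT	0/0	0/1	0|1
8	18400806	rs1799931	G	A	.	PASS	NS=3	GT	0/0	0/0	1|0
8	18400999	rs0000001	C	T	.	PASS	NS=3	GT	0/1	0/0	1/1
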