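##fileformat=VCFv4.2
##source=dmiscreen synthetic example (pooled inviable segregants, ~50x)
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths (ref,alt)">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	pool
chr05	68500	.	A	G	.	PASS	.	AD	1,51
chr05	69500	.	T	C	.	PASS	.	AD	0,48
chr05	70500	.	G	A	.	PASS	.	AD	2,47
chr05	71500	.	C	T	.	PASS	.	AD	0,55
chr05	72500	.	A	C	.	PASS	.	AD	1,46
chr05	73500	.	G	T	.	PASS	.	AD	0,50
chr05	74500	.	T	A	.	PASS	.	AD	0,49
chr05	75500	.	C	G	.	PASS	.	AD	0,52
chr05	76500	.	A	T	.	PASS	.	AD	1,53
chr05	77500	.	G	C	.	PASS	.	AD	0,44
chr05	78500	.	C	A	.	PASS	.	AD	2,50
chr05	79500	.	T	G	.	PASS	.	AD	1,45
chr12	40500	.	A	G	.	PASS	.	AD	24,26
chr12	41500	.	C	T	.	PASS	.	AD	27,22
chr12	42500	.	G	A	.	PASS	.	AD	25,25
chr12	43500	.	T	C	.	PASS	.	AD	21,30
chr12	44500	.	A	T	.	PASS	.	AD	26,23
chr12	45500	.	G	C	.	PASS	.	AD	28,24
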