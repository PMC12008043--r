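##fileformat=VCFv4.2
##source=gbspopgen
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	tox01	tox02	tox03	tox04	tox05	tox06	tox07	tox08	tox09	tox10	tox11	tox12	tox13	tox14	tox15	tox16	tox17	tox18	tox19	tox20	tox21	tox22	tox23	tox24
chr1	2	L7_2	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/1
chr1	3	L4_3	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.
chr1	4	L8_4	A	T	.	PASS	.	GT	1/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.
chr1	5	L1_5	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	7	L3_7	A	T	.	PASS	.	GT	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	8	L6_8	A	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	9	L4_9	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	./.	./.	./.	./.	./.	./.	./.
chr1	10	L2_10	A	T	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	12	L5_12	A	T	.	PASS	.	GT	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	./.	./.	./.
chr1	13	L5_13	A	T	.	PASS	.	GT	1/1	1/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	18	L7_18	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/0	0/0
chr1	19	L7_19	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	20	L2_20	A	T	.	PASS	.	GT	1/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	22	L6_22	A	T	.	PASS	.	GT	1/1	1/1	0/0	0/0	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.
chr1	25	L8_25	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	30	L3_30	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	35	L6_35	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	40	L1_40	A	T	.	PASS	.	GT	1/1	1/1	1/1	1/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	44	L8_44	A	T	.	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
chr1	60	L5_60	A	T	.	PASS	.	GT	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	./.	./.
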