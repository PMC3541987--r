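# toy 4-chromosome cytoband table, UCSC dialect (0-based half-open)
chr1	0	15000000	p14	gneg
chr1	15000000	30000000	p13	gpos50
chr1	30000000	45000000	p12	gneg
chr1	45000000	50000000	p11	acen
chr1	50000000	55000000	q11	acen
chr1	55000000	70000000	q12	gneg
chr1	70000000	85000000	q13	gpos50
chr1	85000000	100000000	q14	gneg
chr2	0	18000000	p13	gneg
chr2	18000000	36000000	p12	gpos50
chr2	36000000	40000000	p11	acen
chr2	40000000	44000000	q11	acen
chr2	44000000	62000000	q12	gneg
chr2	62000000	80000000	q13	gpos50
chr3	0	12000000	p13	gneg
chr3	12000000	24000000	p12	gpos50
chr3	24000000	27000000	p11	acen
chr3	27000000	30000000	q11	acen
chr3	30000000	45000000	q12	gneg
chr3	45000000	60000000	q13	gpos50
chr4	0	10000000	p13	gneg
chr4	10000000	20000000	p12	gpos50
chr4	20000000	23000000	p11	acen
chr4	23000000	26000000	q11	acen
chr4	26000000	38000000	q12	gneg
chr4	38000000	50000000	q13	gpos50
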