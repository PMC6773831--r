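contig	pos	ref	alt	label	set
chrM	1736	A	G	A	phylotree
chrM	235	A	G	A	phylotree
chrM	4824	A	G	A	phylotree
chrM	663	A	G	A	phylotree
chrM	4248	T	C	A	phylotree
chrM	16290	C	T	A	phylotree
chrM	8794	C	T	A	phylotree
chrM	16319	G	A	A	phylotree
chrM	152	T	C	A	phylotree
chrM	3010	G	A	H	phylotree
chrM	9221	A	G	L2	phylotree
chrM	150	C	T	L2	phylotree
chrM	13590	G	A	L2	phylotree
chrM	16390	G	A	L2	phylotree
chrM	8206	G	A	L2	phylotree
chrM	10115	T	C	L2	phylotree
chrM	146	T	C	L2	phylotree
chrM	16311	T	C	L2	phylotree
chrM	2416	T	C	L2	phylotree
chrM	489	T	C	M	phylotree
chrM	10400	C	T	M	phylotree
chrM	14873	T	C	M	phylotree
chrM	15043	G	A	M	phylotree
chrM	12372	G	A	U	phylotree
chrM	9332	C	T	.	snpedia
chrM	10978	A	G	L6	snpedia
chrM	11914	G	A	C	snpedia
chrM	709	G	A	L6/G/N2/T	snpedia
chrM	8392	G	A	Y	snpedia
chrM	6221	T	C	X	snpedia
chrM	1888	G	A	T	snpedia
chrM	13368	G	A	T	snpedia
chrM	14569	G	A	M12'G	snpedia
chrM	5843	A	G	Q	snpedia
chrM	8860	A	G	non-H2a2a1	other
chrM	4759	A	G	non-H2a2a1	other
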