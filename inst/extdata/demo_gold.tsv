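pmid	entrez_id	level	wild	mutant	position	flags
9001001	672	nucleotide	T	G	181	
9001001	672	protein	C	G	61	
9001002	7157	protein	R	H	175	
9001002	7157	nucleotide	G	A	524	
9001003	2099	protein	K	R	303	
9001004	7157	protein	S	P	72	
9001004	19211	protein	A	V	100	nonhuman
9001005	5728	protein	H	Y	123	
9001005	5728	nucleotide	C	T	-34	noncoding
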