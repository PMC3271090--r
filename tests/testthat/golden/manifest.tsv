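gene_id	file	sidecar
GENE0001	GENE0001.wiki.txt	GENE0001.authors.tsv
GENE0002	GENE0002.wiki.txt	GENE0002.authors.tsv
GENE0003	GENE0003.wiki.txt	GENE0003.authors.tsv
GENE0004	GENE0004.wiki.txt	GENE0004.authors.tsv
GENE0005	GENE0005.wiki.txt	GENE0005.authors.tsv
GENE0006	GENE0006.wiki.txt	GENE0006.authors.tsv
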