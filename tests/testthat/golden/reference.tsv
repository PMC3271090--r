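#tax_id	GeneID	GO_ID	Evidence
9606	GENE0001	TOY:0000001	EXP
9606	GENE0001	TOY:0000002	EXP
9606	GENE0001	TOY:0000003	EXP
9606	GENE0002	TOY:0000006	EXP
9606	GENE0003	TOY:0000002	EXP
9606	GENE0005	TOY:0000010	EXP
9606	GENE0006	TOY:0000006	EXP
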