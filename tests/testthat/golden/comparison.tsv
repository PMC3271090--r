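gene_id	term_id	classification	matched_reference_term	is_broader_than_ref	is_narrower_than_ref
GENE0001	TOY:0000001	EXACT	TOY:0000001	TRUE	FALSE
GENE0001	TOY:0000004	MORE_SPECIFIC	TOY:0000001	FALSE	TRUE
GENE0001	TOY:0000008	MORE_SPECIFIC	TOY:0000001	FALSE	TRUE
GENE0002	TOY:0000006	EXACT	TOY:0000006	FALSE	FALSE
GENE0002	TOY:0000010	NONE	NA	FALSE	FALSE
GENE0002	TOY:0000011	MORE_SPECIFIC	TOY:0000006	FALSE	TRUE
GENE0003	TOY:0000002	EXACT	TOY:0000002	FALSE	FALSE
GENE0003	TOY:0000010	MORE_SPECIFIC	TOY:0000002	FALSE	TRUE
GENE0005	TOY:0000004	MORE_GENERAL	TOY:0000010	TRUE	FALSE
GENE0005	TOY:0000010	EXACT	TOY:0000010	FALSE	FALSE
GENE0006	TOY:0000002	MORE_GENERAL	TOY:0000006	TRUE	FALSE
GENE0006	TOY:0000004	NONE	NA	FALSE	FALSE
GENE0006	TOY:0000007	MORE_SPECIFIC	TOY:0000006	FALSE	TRUE
GENE0006	TOY:0000008	NONE	NA	FALSE	FALSE
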