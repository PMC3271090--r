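gene_id	ontology	term_id	term_label	n_mentions	first_evidence_sentence
GENE0001	ontology	TOY:0000001	bepod	1	Oyster powder bepod orange dinner planet stone.
GENE0001	ontology	TOY:0000004	loduvod dafuned	1	Pocket marble candle loduvod dafuned tender cotton sister lemon.
GENE0001	ontology	TOY:0000008	riduk fulatop	1	Narrow bridge riduk fulatop pencil candle vivid.
GENE0002	ontology	TOY:0000006	gipusut	1	Reason gentle jungle puzzle gipusut kitchen needle silver.
GENE0002	ontology	TOY:0000010	lubup	1	Needle hunter lubup table mirror orbit fabric.
GENE0002	ontology	TOY:0000011	resarip	1	Bridge orange resarip saddle tender forest.
GENE0003	ontology	TOY:0000002	nomak giradas	2	Vivid summer lumber nomak giradas circle jacket.
GENE0003	ontology	TOY:0000010	lubup	1	Orange thunder sunset lubup glacier table reason.
GENE0005	ontology	TOY:0000004	loduvod dafuned	1	Factor pencil outline square loduvod dafuned analysis steady.
GENE0005	ontology	TOY:0000010	lubup	1	Summer village lubup factor mountain stone.
GENE0006	ontology	TOY:0000002	nomak giradas	1	String palace nomak giradas thunder candle autumn needle.
GENE0006	ontology	TOY:0000004	loduvod dafuned	1	Flower honest outline lecture loduvod dafuned little cotton string meadow.
GENE0006	ontology	TOY:0000007	ketelad zunop	1	Mirror jacket street ketelad zunop planet shelter jacket cloudy.
GENE0006	ontology	TOY:0000008	riduk fulatop	1	Flower hollow garden riduk fulatop turtle orbit.
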