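term_id	a_base	b_base	c_base	d_base	a_aug	b_aug	c_aug	d_aug	p_base	p_aug	odds_ratio_base	odds_ratio_aug	significant_base	significant_aug
TOY:0000001	1	0	0	5	1	0	0	5	0.166667	0.166667	Inf	Inf	FALSE	FALSE
TOY:0000002	1	1	1	3	1	1	1	3	0.6	0.6	3	3	FALSE	FALSE
TOY:0000003	0	0	1	5	0	0	1	5	1	1	NA	NA	FALSE	FALSE
TOY:0000006	1	0	1	4	1	0	1	4	0.333333	0.333333	Inf	Inf	FALSE	FALSE
TOY:0000010	1	2	0	3	1	2	0	3	0.5	0.5	Inf	Inf	FALSE	FALSE
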