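sentence_index	author	imported_flag
0	ProteinBoxBot	TRUE
1	editor_5	FALSE
2	ProteinBoxBot	TRUE
3	editor_5	FALSE
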