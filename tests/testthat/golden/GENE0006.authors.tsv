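sentence_index	author	imported_flag
0	editor_6	FALSE
1	editor_6	FALSE
2	editor_6	FALSE
3	editor_6	FALSE
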