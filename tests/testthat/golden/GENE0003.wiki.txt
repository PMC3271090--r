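Orange thunder sunset lubup glacier table reason. Vivid summer lumber nomak giradas circle jacket. Velvet eleven stable hunter nomak giradas lumber square mountain.
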