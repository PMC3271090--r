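'''Narrow''' bridge riduk fulatop pencil candle [[topic|vivid]]<ref>cite</ref>. Mountain marble engine ketelad zunop reason autumn stone. Oyster powder bepod orange dinner planet stone. '''Pocket''' marble candle loduvod dafuned tender cotton sister [[topic|lemon]]<ref>cite</ref>.
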