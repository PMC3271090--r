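'''Mirror''' jacket street ketelad zunop planet shelter jacket [[topic|cloudy]]<ref>cite</ref>. String palace nomak giradas thunder candle autumn needle. '''Flower''' hollow garden riduk fulatop turtle [[topic|orbit]]<ref>cite</ref>. Flower honest outline lecture loduvod dafuned little cotton string meadow.
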