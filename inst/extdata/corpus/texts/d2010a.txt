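The grateful community thanked the elderly volunteer after a long celebration.
Neighbours stayed behind to sweep the hall and stack every chair.
A light rain fell over the quiet town in the evening.
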