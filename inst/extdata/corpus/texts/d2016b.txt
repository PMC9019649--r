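A new bridge opened across the channel after years of construction.
Cyclists and joggers crossed at dawn to watch boats pass underneath.
Engineers praised the design while tourists photographed the towers.
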