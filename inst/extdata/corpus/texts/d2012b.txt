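Harvest season brought farmers to the weekend market early.
Stalls offered pumpkins, apples, and bread while a band played by the fountain.
Shoppers carried heavy baskets home before the afternoon heat arrived.
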