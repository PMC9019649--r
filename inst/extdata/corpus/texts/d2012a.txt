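The committee honoured the elderly painter with a respected halcyon award.
The gallery hung new canvases beside the staircase for the show.
Collectors travelled from distant cities to attend the opening night.
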