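The tired caregiver watched the elderly patient endure sickness and slow decline.
Machines hummed softly beside the narrow bed through the night.
Relatives took turns reading aloud until the lamps were dimmed.
A kettle warmed in the corner while rain tapped on the glass.
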