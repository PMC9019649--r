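A street parade marked the festival season once again.
Crowds lined the road and cheered while drummers marched past the market stalls.
Lanterns glowed above the river until well after midnight.
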