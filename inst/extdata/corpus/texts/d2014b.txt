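The transport authority unveiled a refurbished railway station downtown.
Commuters tested wider platforms while engineers checked the signalling gear.
A ribbon was cut at noon and balloons drifted over the concourse.
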