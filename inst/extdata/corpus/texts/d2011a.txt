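Residents admired the elderly teacher for wise and active service.
The school opened its garden to visitors during the spring fair.
Children planted beans along the fence and watered them every morning.
Parents lingered by the gate and talked about the coming holidays.
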