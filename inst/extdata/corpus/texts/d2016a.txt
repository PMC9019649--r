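Nurses comforted the elderly patient after a painful illness and sudden sickness.
The ward grew quiet once visiting hours ended each evening.
Orderlies wheeled supply carts down the corridor past the closed doors.
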