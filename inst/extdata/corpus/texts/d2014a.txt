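Nurses visited the elderly patients during the new clinic programme.
Appointment letters went out to households across several districts that month.
Waiting rooms were repainted and extra benches placed beside the pharmacy counter.
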