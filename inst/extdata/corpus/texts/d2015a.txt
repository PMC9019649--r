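Doctors treated the elderly woman for a chronic illness at the hospital.
Ward staff kept careful charts and reviewed them during every shift.
Her family brought flowers and sat with her through the long afternoons.
Outside the window a fig tree shaded the gravel courtyard below.
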