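Everyone cheered the elderly hero whose grateful smile inspired the grand parade.
Flags hung from balconies along the whole avenue that week.
Bands practised for days so the marching columns would keep perfect time.
Vendors sold paper windmills and cold drinks along the crowded route.
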