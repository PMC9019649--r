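doc_id	year	source	path
d2010a	2010	fixture	texts/d2010a.txt
d2010b	2010	fixture	texts/d2010b.txt
d2011a	2011	fixture	texts/d2011a.txt
d2012a	2012	fixture	texts/d2012a.txt
d2012b	2012	fixture	texts/d2012b.txt
d2013a	2013	fixture	texts/d2013a.txt
d2014a	2014	fixture	texts/d2014a.txt
d2014b	2014	fixture	texts/d2014b.txt
d2015a	2015	fixture	texts/d2015a.txt
d2016a	2016	fixture	texts/d2016a.txt
d2016b	2016	fixture	texts/d2016b.txt
d2017a	2017	fixture	texts/d2017a.txt
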