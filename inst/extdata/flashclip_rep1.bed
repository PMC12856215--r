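chr1	100	130	f1	4	+
chr1	130	160	f2	6	+
chr1	500	530	f3	9	+
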