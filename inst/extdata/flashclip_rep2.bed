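chr1	110	150	f4	25	+
chr1	505	535	f5	12	+
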