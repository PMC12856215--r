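chr1	120	170	s5	55	+
chr1	520	560	s6	45	+
chr1	905	955	s7	60	+
chr2	90	150	s8	90	-
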