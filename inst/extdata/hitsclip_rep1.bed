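chr1	100	120	c1	5	+
chr1	120	140	c2	3	+
chr1	800	820	c3	4	+
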