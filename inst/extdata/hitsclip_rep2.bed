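chr1	110	130	c4	6	+
chr1	790	830	c5	2	+
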