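chr1	105	125	c6	4	+
chr1	2000	2020	c7	9	+
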