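chr1	100	150	s1	50	+
chr1	500	550	s2	40	+
chr1	900	950	s3	39	+
chr2	100	160	s4	80	-
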