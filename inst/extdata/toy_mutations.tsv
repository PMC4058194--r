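sample	g1	g2	g3	g4
s1	1	0	0	0
s2	1	0	0	0
s3	0	1	1	0
s4	0	0	1	0
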