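#TIP_ID	s1	s2
otuA	3	0
otuB	1	0
otuC	0	1
otuD	0	3
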