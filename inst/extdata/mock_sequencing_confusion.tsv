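control	tp	fp	fn
R1P1Zymoseq	8	4	0
R1P2Zymoseq	8	8	0
R1P3Zymoseq	7	4	1
R1P4Zymoseq	8	6	0
R2P1Zymoseq	8	1	0
R2P2Zymoseq	7	0	1
R2P3Zymoseq	8	3	0
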