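control	tp	fp	fn
R1P1Zymoex	7	15	1
R1P2Zymoex	8	3	0
R1P3Zymoex	8	3	0
R1P4Zymoex	7	0	1
R2P1Zymoex	7	3	1
R2P2Zymoex	8	0	0
R2P3Zymoex	8	2	0
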