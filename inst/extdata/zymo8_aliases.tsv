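alias	species
Escherichia coli	Escherichia/Shigella coli
Lactobacillus fermentum	Limosilactobacillus fermentum
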