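Bifidobacterium longum
Bifidobacterium breve
Bifidobacterium bifidum
Bacteroides fragilis
Bacteroides vulgatus
Bacteroides dorei
Parabacteroides distasonis
Klebsiella pneumoniae
Klebsiella oxytoca
Enterobacter cloacae
Veillonella parvula
Veillonella atypica
Streptococcus salivarius
Streptococcus parasanguinis
Lactobacillus gasseri
Clostridium perfringens
Clostridioides difficile
Ruminococcus gnavus
Faecalibacterium prausnitzii
Akkermansia muciniphila
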