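Cutibacterium acnes
Ralstonia pickettii
Bradyrhizobium japonicum
Streptococcus mitis
Streptococcus oralis
Corynebacterium tuberculostearicum
Micrococcus luteus
Acinetobacter johnsonii
Acinetobacter lwoffii
Sphingomonas paucimobilis
Methylobacterium radiotolerans
Pelomonas saccharophila
Burkholderia cepacia
Stenotrophomonas maltophilia
Delftia acidovorans
Comamonas testosteroni
Herbaspirillum seropedicae
Janthinobacterium lividum
Massilia timonae
Caulobacter vibrioides
Brevundimonas diminuta
Ochrobactrum anthropi
Phyllobacterium myrsinacearum
Mesorhizobium loti
Rhizobium leguminosarum
Agrobacterium tumefaciens
Paracoccus denitrificans
Rhodococcus erythropolis
Dietzia maris
Gordonia bronchialis
Tsukamurella paurometabola
Kocuria rhizophila
Rothia mucilaginosa
Dermacoccus nishinomiyaensis
Kytococcus sedentarius
Brachybacterium faecium
Microbacterium oxydans
Curtobacterium flaccumfaciens
Leifsonia xyli
Frigoribacterium faeni
Aerococcus viridans
Facklamia hominis
Gemella haemolysans
Granulicatella adiacens
Abiotrophia defectiva
Anoxybacillus flavithermus
Geobacillus stearothermophilus
Paenibacillus polymyxa
Lysinibacillus sphaericus
Solibacillus silvestris
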