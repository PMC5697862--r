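taxon	carriers	total
Proboscidea	37	37
Carnivora	438	1005
Pholidota	4	11
Primates	50	604
Neoteleostei	320	1886
Acipenseriformes	2	33
Perissodactyla	9	299
Chiroptera	2	87
Cryptodira	3	150
Squamata	7	379
Caudata	2	186
Anguilliformes	2	217
Ostariophysi	9	1261
Rodentia	2	454
Cetartiodactyla	2	1599
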