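species	common_name	n_before_qc	n_after_qc
Anguilla anguilla	European Eel	55	54
Anguilla rostrata	American Eel	51	51
Balaenoptera physalus	Fin Whale	154	154
Bison bison	Bison	34	34
Bos grunniens	Yak	83	83
Bos taurus	Cow	275	275
Canis lupus familiaris	Dog	391	391
Clupea harengus	Atlantic Herring	100	100
Coregonus lavaretus	European whitefish	81	80
Equus caballus	Horse	254	245
Gallus gallus	Red Jungle Fowl	66	66
Glyphis glyphis	Speartooth Shark	94	94
Hypophthalmichthys molitrix	Silver carp	30	29
Hypophthalmichthys nobilis	Bighead carp	36	35
Macaca fascicularis	Crab-eating macaque	44	44
Mus musculus	Mouse	53	50
Mus musculus domesticus	House mouse	59	59
Myodes glareolus	Bank vole	35	35
Orcinus orca	Killer Whale	87	87
Ovis aries	Sheep	94	94
Pan paniscus	Bonobo	54	54
Pan troglodytes schweinfurthii	Eastern chimpanzee	33	33
Pan troglodytes troglodytes	Central chimpanzee	56	54
Pan troglodytes verus	Western chimpanzee	30	30
Rattus norvegicus	Brown Rat	66	66
Sus scrofa	Wild Boar	150	150
Syncerus caffer	African buffalo	45	45
Tursiops truncatus	Common bottlenose Dolphin	50	50
Urocyon littoralis catalinae	Island Fox	41	41
Urocyon littoralis clementae	Island Fox	33	33
Urocyon littoralis santacruzae	Island Fox	42	42
Ursus arctos	Brown Bear	74	74
Ursus spelaeus	Cave Bear	34	20
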