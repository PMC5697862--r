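family	species	pct_3243G	pct_3253C
Canidae	Canis lupus familiaris	15	100
Canidae	Canis lupus	0	100
Canidae	Canis lupus campestris	0	100
Canidae	Canis lupus desertorum	0	100
Canidae	Canis lupus lupus	0	100
Canidae	Canis lupus chanco	0	100
Canidae	Canis lupus laniger	0	100
Canidae	Canis latrans	0	20
Phocidae	Lobodon carcinophaga	100	100
Phocidae	Hydrurga leptonyx	0	100
Phocidae	Leptonychotes weddellii	100	100
Phocidae	Mirounga leonina	0	100
Ursidae	Ursus thibetanus	0	8
Felidae	Puma concolor	0	100
Felidae	Felis catus	0	100
Felidae	Acinonyx jubatus	0	100
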