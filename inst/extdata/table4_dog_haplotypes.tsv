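label	3230	3239	3243	3290	count
Group1	G	G	A	T	328
Group2	G	-	A	T	3
Group3	G	G	A	C	2
Group4	-	G	A	A	1
Group5	G	-	G	T	2
Group6	G	G	G	T	55
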