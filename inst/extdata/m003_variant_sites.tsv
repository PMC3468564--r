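site_id	position	state_H	state_C1	state_C2	state_chimp	aa_H	aa_C1	aa_C2	aa_chimp
rs1667354	479	A	G	G	A	Asp	splicing	splicing	Asp
rs935706	1039	G	A	A	G	Ala	Thr	Thr	Ala
rs935707	1130	G	A	A	A	Arg	His	His	His
rs1667363	1273	A	T	T	T	Ser	Cys	Cys	Cys
rs1667364	1280	C	A	A	A	Ala	Glu	Glu	Glu
rs16971886	1382	G	G	A	G	Arg	Arg	His	Arg
syn1404	1404	T	T	T	C	-	-	-	-
rs10405238	1462	T	G	T	T	Tyr	Asp	Tyr	Tyr
rs1345748	1604	G	A	A	A	Cys	Tyr	Tyr	Tyr
rs1363752	1706	A	G	G	G	Glu	Gly	Gly	Gly
rs1644698	1879	C	G	G	G	Pro	Ala	Ala	Ala
rs1363753	1888	G	C	C	C	Gly	Arg	Arg	Arg
rs1667366	1906	T	C	C	C	Stop	Arg	Arg	Arg
rs3745770	1972	C	C	G	C	-	Arg	Gly	Arg
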