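species	symbol	assay	result
human	BAK1	screen	pass
human	BAK1	pulldown	pass
human	BAK1	luciferase	pass
human	CDC25C	screen	pass
human	CDC25C	pulldown	pass
human	CDC25C	luciferase	pass
human	EDN1	screen	pass
human	EDN1	pulldown	pass
human	EDN1	luciferase	fail
human	IGFBP3	screen	pass
human	IGFBP3	pulldown	pass
human	IGFBP3	luciferase	fail
human	MRE11A	screen	pass
human	MRE11A	pulldown	pass
human	MRE11A	luciferase	fail
human	PPP1CA	screen	pass
human	PPP1CA	pulldown	pass
human	PPP1CA	luciferase	pass
human	PPP2CA	screen	pass
human	PPP2CA	pulldown	pass
human	PPP2CA	luciferase	pass
human	PRKRA	screen	pass
human	PRKRA	pulldown	pass
human	PRKRA	luciferase	pass
human	PUMA	screen	pass
human	PUMA	pulldown	pass
human	PUMA	luciferase	pass
human	TDG	screen	pass
human	TDG	pulldown	pass
human	TDG	luciferase	pass
human	TP53	screen	pass
human	TP53	pulldown	pass
human	TP53	luciferase	pass
human	TP53INP1	screen	pass
human	TP53INP1	pulldown	pass
human	TP53INP1	luciferase	pass
human	ZAC1	screen	pass
human	ZAC1	pulldown	pass
human	ZAC1	luciferase	pass
human	UNNAMED_H1	screen	pass
human	UNNAMED_H1	pulldown	fail
human	UNNAMED_H2	screen	pass
human	UNNAMED_H2	pulldown	fail
human	UNNAMED_H3	screen	pass
human	UNNAMED_H3	pulldown	fail
human	UNNAMED_H4	screen	pass
human	UNNAMED_H4	pulldown	fail
human	UNNAMED_H5	screen	pass
human	UNNAMED_H5	pulldown	fail
human	UNNAMED_H6	screen	pass
human	UNNAMED_H6	pulldown	fail
human	UNNAMED_H7	screen	pass
human	UNNAMED_H7	pulldown	fail
human	UNNAMED_H8	screen	pass
human	UNNAMED_H8	pulldown	fail
human	UNNAMED_H9	screen	pass
human	UNNAMED_H9	pulldown	fail
mouse	Bak1	screen	pass
mouse	Bak1	pulldown	pass
mouse	Bak1	luciferase	pass
mouse	Hspa5	screen	pass
mouse	Hspa5	pulldown	pass
mouse	Hspa5	luciferase	fail
mouse	Itch	screen	pass
mouse	Itch	pulldown	pass
mouse	Itch	luciferase	pass
mouse	Ppp1ca	screen	pass
mouse	Ppp1ca	pulldown	pass
mouse	Ppp1ca	luciferase	pass
mouse	Ppp2ca	screen	pass
mouse	Ppp2ca	pulldown	pass
mouse	Ppp2ca	luciferase	pass
mouse	Prkra	screen	pass
mouse	Prkra	pulldown	pass
mouse	Prkra	luciferase	pass
mouse	Puma	screen	pass
mouse	Puma	pulldown	pass
mouse	Puma	luciferase	pass
mouse	Sel1l	screen	pass
mouse	Sel1l	pulldown	pass
mouse	Sel1l	luciferase	pass
mouse	Sp1	screen	pass
mouse	Sp1	pulldown	pass
mouse	Sp1	luciferase	fail
mouse	Tdg	screen	pass
mouse	Tdg	pulldown	pass
mouse	Tdg	luciferase	pass
mouse	Trp53inp1	screen	pass
mouse	Trp53inp1	pulldown	pass
mouse	Trp53inp1	luciferase	pass
mouse	Unnamed_m1	screen	pass
mouse	Unnamed_m1	pulldown	fail
mouse	Unnamed_m2	screen	pass
mouse	Unnamed_m2	pulldown	fail
mouse	Trp53	screen	fail
zebrafish	cdc25c	screen	pass
zebrafish	cdc25c	pulldown	pass
zebrafish	cdc25c	luciferase	pass
zebrafish	cdkn2c	screen	pass
zebrafish	cdkn2c	pulldown	pass
zebrafish	cdkn2c	luciferase	pass
zebrafish	gtf2h1	screen	pass
zebrafish	gtf2h1	pulldown	pass
zebrafish	gtf2h1	luciferase	pass
zebrafish	hspa5	screen	pass
zebrafish	hspa5	pulldown	pass
zebrafish	hspa5	luciferase	pass
zebrafish	itch	screen	pass
zebrafish	itch	pulldown	pass
zebrafish	itch	luciferase	fail
zebrafish	ppp1ca	screen	pass
zebrafish	ppp1ca	pulldown	pass
zebrafish	ppp1ca	luciferase	pass
zebrafish	sel1l	screen	pass
zebrafish	sel1l	pulldown	pass
zebrafish	tp53	screen	pass
zebrafish	tp53	pulldown	pass
zebrafish	tp53	luciferase	pass
zebrafish	ccnc	screen	pass
zebrafish	ccnc	pulldown	fail
zebrafish	ccnc	luciferase	pass
zebrafish	unnamed_z1	screen	pass
zebrafish	unnamed_z1	pulldown	fail
zebrafish	unnamed_z2	screen	pass
zebrafish	unnamed_z2	pulldown	fail
zebrafish	unnamed_z3	screen	pass
zebrafish	unnamed_z3	pulldown	fail
zebrafish	unnamed_z4	screen	pass
zebrafish	unnamed_z4	pulldown	fail
zebrafish	unnamed_z5	screen	pass
zebrafish	unnamed_z5	pulldown	fail
zebrafish	prkra	screen	fail
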