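species	symbol	canonical
human	BAK1	Bak1
human	CDC25C	Cdc25c
human	EDN1	Edn1
human	IGFBP3	Igfbp3
human	MRE11A	Mre11a
human	PPP1CA	Ppp1ca
human	PPP2CA	Ppp2ca
human	PRKRA	Prkra
human	PUMA	Puma
human	TDG	Tdg
human	TP53	Tp53
human	TP53INP1	Tp53inp1
human	ZAC1	Zac1
human	UNNAMED_H1	Unnamed_h1
human	UNNAMED_H2	Unnamed_h2
human	UNNAMED_H3	Unnamed_h3
human	UNNAMED_H4	Unnamed_h4
human	UNNAMED_H5	Unnamed_h5
human	UNNAMED_H6	Unnamed_h6
human	UNNAMED_H7	Unnamed_h7
human	UNNAMED_H8	Unnamed_h8
human	UNNAMED_H9	Unnamed_h9
mouse	Bak1	Bak1
mouse	Hspa5	Hspa5
mouse	Itch	Itch
mouse	Ppp1ca	Ppp1ca
mouse	Ppp2ca	Ppp2ca
mouse	Prkra	Prkra
mouse	Puma	Puma
mouse	Sel1l	Sel1l
mouse	Sp1	Sp1
mouse	Tdg	Tdg
mouse	Trp53inp1	Tp53inp1
mouse	Unnamed_m1	Unnamed_m1
mouse	Unnamed_m2	Unnamed_m2
mouse	Trp53	Tp53
zebrafish	cdc25c	Cdc25c
zebrafish	cdkn2c	Cdkn2c
zebrafish	gtf2h1	Gtf2h1
zebrafish	hspa5	Hspa5
zebrafish	itch	Itch
zebrafish	ppp1ca	Ppp1ca
zebrafish	sel1l	Sel1l
zebrafish	tp53	Tp53
zebrafish	ccnc	Ccnc
zebrafish	unnamed_z1	Unnamed_z1
zebrafish	unnamed_z2	Unnamed_z2
zebrafish	unnamed_z3	Unnamed_z3
zebrafish	unnamed_z4	Unnamed_z4
zebrafish	unnamed_z5	Unnamed_z5
zebrafish	prkra	Prkra
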