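canonical	functional_class	process_effect
Bak1	apoptosis_regulator	promotes
Igfbp3	apoptosis_regulator	promotes
Puma	apoptosis_regulator	promotes
Prkra	apoptosis_regulator	promotes
Tp53	apoptosis_regulator	promotes
Tp53inp1	apoptosis_regulator	promotes
Zac1	apoptosis_regulator	promotes
Itch	apoptosis_regulator	inhibits
Hspa5	apoptosis_regulator	inhibits
Cdkn2c	cell_cycle_regulator	promotes
Ppp1ca	cell_cycle_regulator	promotes
Sel1l	cell_cycle_regulator	promotes
Mre11a	cell_cycle_regulator	promotes
Ppp2ca	cell_cycle_regulator	promotes
Tdg	cell_cycle_regulator	promotes
Gtf2h1	cell_cycle_regulator	promotes
Ccnc	cell_cycle_regulator	inhibits
Cdc25c	cell_cycle_regulator	inhibits
Edn1	cell_cycle_regulator	inhibits
Sp1	cell_cycle_regulator	inhibits
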