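gene	species	site_seq	seed_binding_seq
Ppp1ca	human	ACUGAUCUCAGGGAUCCAGU	CUCAGGG
Ppp1ca	mouse	ACUGAUCUCAGGGAUCCAGA	CUCAGGG
Ppp1ca	zebrafish	ACGUCGCUCAGGGCGAUGGU	CUCAGGG
Prkra	human	GAUCUCAGGGACUGCAU	CUCAGGG
Prkra	mouse	GAUCUCAGGGACUGCAC	CUCAGGG
Prkra	zebrafish	AGGAGGUUUUUUUAAGA	NA
Tp53	human	GUAACAUCUCAGGGCAUAAUGGACU	CUCAGGG
Tp53	mouse	CAUGGAUCACAGGAAUUGGCUCAGA	CACAGGA
Tp53	zebrafish	AAAAACGCUCAGGGAAAAUUGGAGU	CUCAGGG
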