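mirna_group	mirna_direction	target_gene	target_direction	description
osa-miR156l	Up	LOC_Os01g06550.1	Down	NF-X1-type zinc finger protein, putative
osa-miR156l	Up	LOC_Os02g34860.1	Down	Regulator of chromosome condensation domain containing protein
osa-miR160f	Down	LOC_Os04g43910.1	Up	Auxin response factor, putative
osa-miR160f	Down	LOC_Os06g49840.1	Up	OsMADS16 - MADS-box family gene with MIKCc type-box
osa-miR164a,b	Down	LOC_Os01g62660.1	Up	MYB family transcription factor, putative
osa-miR172a,b	Down	LOC_Os03g60430.2	Up	AP2 domain containing protein
osa-miR172a,b	Down	LOC_Os04g55560.4	Up	AP2 domain containing protein
osa-miR390	Down	LOC_Os02g10100.1	Up	Leucine-rich repeat receptor protein kinase EXS precursor, putative
osa-miR390	Down	LOC_Os06g03970.1	Up	Receptor-like protein kinase 5 precursor, putative
osa-miR390	Down	LOC_Os01g33110.1	Up	Receptor-like protein kinase 5 precursor, putative
osa-miR408	Down	LOC_Os08g37670.1	Up	Plastocyanin-like domain containing protein, putative
osa-miR408	Down	LOC_Os01g54430.1	Up	Plastocyanin-like domain containing protein, putative
oru-miR135	Up	LOC_Os05g27930.1	Down	AP2 domain containing protein
oru-miR135	Up	LOC_Os01g67240.1	Down	Formin-like protein 1 precursor, putative
oru-miR135	Up	LOC_Os07g38800.1	Down	Lectin-like receptor kinase, putative
oru-miR135	Up	LOC_Os08g23180.1	Down	Fasciclin-like arabinogalactan protein 8 precursor, putative
oru-miR135	Up	LOC_Os11g45740.1	Down	MYB family transcription factor, putative
oru-miR139	Up	LOC_Os01g10580.1	Down	B-box zinc finger family protein, putative
oru-miR180	Up	LOC_Os06g24070.1	Down	myb-like DNA-binding domain containing protein
oru-miR4	Down	LOC_Os09g39410.1	Up	Male sterility protein, putative
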