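mirna_acc	target_acc	expectation	upe	mirna_start	mirna_end	target_start	target_end	mirna_fragment	target_fragment	inhibition
bna-miR169a	BnaA03g33640D	4	21.988	1	20	204	223	CAGCCAAGGAUGACUUGCCG	AGGCAAGCCAAACUUGGCUG	Translation
bna-miR169b	BnaA03g33640D	4	21.988	1	20	204	223	CAGCCAAGGAUGACUUGCCG	AGGCAAGCCAAACUUGGCUG	Translation
bna-miR169c	BnaA03g33640D	3.5	21.988	1	20	204	223	UAGCCAAGGAUGACUUGCCU	AGGCAAGCCAAACUUGGCUG	Translation
bna-miR169d	BnaA03g33640D	3.5	21.988	1	20	204	223	UAGCCAAGGAUGACUUGCCU	AGGCAAGCCAAACUUGGCUG	Translation
bna-miR169e	BnaA03g33640D	3.5	21.988	1	20	204	223	UAGCCAAGGAUGACUUGCCU	AGGCAAGCCAAACUUGGCUG	Translation
bna-miR169f	BnaA03g33640D	3.5	21.988	1	20	204	223	UAGCCAAGGAUGACUUGCCU	AGGCAAGCCAAACUUGGCUG	Translation
gma-miR171b-3p	Glyma.03G139700	3	24.213	1	20	168	186	CGAGCCGAAUCAAUAUCACU	AGUGAUAUUGAUU-GGCUUG	Cleavage
gma-miR171b-3p	Glyma.19G142500	3	22.553	1	20	210	228	CGAGCCGAAUCAAUAUCACU	AGUGAUAUUGAUU-GGCUUG	Cleavage
gma-miR5775	Glyma.03G139700	1	14.793	1	21	264	284	AGCUUCUCUACAGAAAAUAUA	UAUAUUUUCAGUAGAGAAGCU	Cleavage
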