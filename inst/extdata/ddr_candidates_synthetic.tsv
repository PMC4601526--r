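mirna_id	stemloop_id	sequence	coverage
miR-34c-5p	miR-34c	CGGTCACACCAGGAGAAACTCG	4385
1947411_x4	1947411_x4	TAAAACTTCAAACATCACGTAT	3182
miR-486-5p	miR-486	GATTACAACTCCCATGAAAAGC	6100
miR-148a-3p	miR-148a	CACCCCTCGCGACCTCATGAGG	2672
miR-152	miR-152	AGTTGGGGCTTAAATGGAGTCT	1187
miR-1247-3p	miR-1247	ATGCGAAAGCGCGCCTTATATG	4277
miR-1	miR-1	GGTATACGAATGAGGGCGACCA	2091
let-7a-3p	let-7a	TCGGGACTGTTGTTAACTGATA	2259
miR-365a-3p	miR-365a	CAAAATTTACTCCACTTTACTG	4178
miR-3184-3p	miR-3184	ACGGTTGACCCGCTGCTGCTTT	1820
miR-423-5p	miR-423	AACCTCGACATGACGAAAGCCC	3770
miR-139-5p	miR-139	GATACCTTTGCTAATATTTTTA	4200
miR-125b-5p	miR-125b	ACATGTAAGGTTTCACCGACAG	1535
miR-191-5p	miR-191	TACACTGCAGTCATGTGCGCCA	893
miR-34a-5p	miR-34a	AGAGTCCTGTGCTGAGAATAGG	4591
miR-96-5p	miR-96	TATTAGTCAGTCGATTAGACTG	1613
miR-192-5p	miR-192	TCACGTTCTATCTAGTCGTAAA	3068
miR-215	miR-215	CGTTTTGCGTAGCCGAGTTTAT	1129
miR-148b-3p	miR-148b	ATCAAAGCCTTGACAATCAGAA	3165
miR-146a-5p	miR-146a	GCTGGTTGACTGGCGCTCTCGC	1138
miR-139-3p	miR-139	CACTACGGGCTTACGGGAGCCA	310
miR-486-3p	miR-486	ACAATTGACCAGATCTTCTACC	95
miR-365b-3p	miR-365b	CAAAATTTACTCCACTTTACTG	2939
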