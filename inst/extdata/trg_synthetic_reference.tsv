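id	segment_type	family	family_index	functional_status	anchor_offset	rss	note	locus_start	locus_end	motif_block
TRGV4.1	V	TRGV4	1	pseudogene	NA	NA	NA	0	120	M1
TRGV1.1	V	TRGV1	1	pseudogene	NA	NA	NA	520	640	M1
TRGV3.1	V	TRGV3	1	functional	114	CACCGTGACCGTGGTACCTCAAGCGGCCCGACAAAAACC	NA	1040	1160	M1
TRGV2.1	V	TRGV2	1	functional	114	CACGGTGGTTACAACCCCACTGGGCTACCTACAAAAACC	NA	1560	1680	M1
TRGV2.2	V	TRGV2	2	pseudogene	NA	NA	NA	2080	2200	M1
TRGV2.3	V	TRGV2	3	pseudogene	NA	NA	NA	2600	2720	M1
TRGV2.4	V	TRGV2	4	functional	114	CACAGTGCGTCACCAGGATCGCGATGAGATACAAAAACC	NA	3120	3240	M1
TRGV4.2	V	TRGV4	2	functional	114	CACAGCGTCTCGCTGTGCCAGTTTTTCATGACAAAAACC	NA	3640	3760	M2
TRGV1.2	V	TRGV1	2	not_detected_expressed	114	CACAGTACGTCCTGTCGTATACAATGAGGGGCACAAACC	NA	4160	4280	M2
TRGV3.2	V	TRGV3	2	functional	114	CACAGTGTAGCCCATGGTGGGTAAACTGTAACAAAAACC	NA	4680	4800	M2
TRGV2.5	V	TRGV2	5	pseudogene	NA	NA	NA	5200	5320	M2
TRGV2.6	V	TRGV2	6	pseudogene	NA	NA	NA	5720	5840	M2
TRGV2.7	V	TRGV2	7	functional	114	CATAGTGTTACTTAGGAAGCGACGTACAATACAAAAACC	NA	6240	6360	M2
TRGV2.8	V	TRGV2	8	functional	114	CACAGTGAATGACTGCTGTCCACGAGATGGACAAAACCC	NA	6760	6880	M2
TRGV4.3	V	TRGV4	3	pseudogene	NA	NA	NA	7280	7400	M3
TRGV1.3	V	TRGV1	3	functional	114	CCCAGTGTGCAGTCTAAGCAGTTAGTGCATACAAAAACC	NA	7800	7920	M3
TRGV3.3	V	TRGV3	3	functional	114	CACAGTGTTATTCGCGGAACCCTCTTGCGCACAAAATCC	NA	8320	8440	M3
TRGV2.9	V	TRGV2	9	not_detected_expressed	114	CACAGTGGCGAGCAATCACTTGACATCGGAACAAAAACC	NA	8840	8960	M3
TRGV2.10	V	TRGV2	10	pseudogene	NA	NA	deletion-bearing pseudogene; family assigned from sequence upstream of the deletion only (synthetic placeholder sequence)	9360	9480	M3
TRGV2.11	V	TRGV2	11	functional	114	CACAGCGATAGCCATCGATGCTGAGTGTTGAAAAAAACC	NA	9880	10000	M3
TRGV2.12	V	TRGV2	12	functional	114	CACAGTTTCTTTTTACTGAATATTAAGCCCACAAAAACC	NA	10400	10520	M3
TRGV4.4	V	TRGV4	4	functional	114	CACAGTGCAGTACGGTAACTGCCCTCCTTCACAAAAACC	NA	10920	11040	M4
TRGV1.4	V	TRGV1	4	pseudogene	NA	NA	deletion-bearing pseudogene; family assigned from sequence upstream of the deletion only (synthetic placeholder sequence)	11440	11560	M4
TRGV3.4	V	TRGV3	4	functional	114	CACTGTGCGCGAACACATGCCCGAGACGGCACAATAACC	NA	11960	12080	M4
TRGV2.13	V	TRGV2	13	functional	114	CACAATGTCTTTCATTTAAATGGAAGGTATAAATAAACC	NA	12480	12600	M4
TRGV2.14	V	TRGV2	14	functional	114	TACAGTGTCCTGCCGTGGGAGCATACTCCTACAAAACCC	NA	13000	13120	M4
TRGV2.15	V	TRGV2	15	functional	114	CACAGTGAACTGACTTGGCCTTACGACACAACTAAAACC	NA	13520	13640	M4
TRGV2.16	V	TRGV2	16	pseudogene	NA	NA	NA	14040	14160	M4
TRGV4.5	V	TRGV4	5	pseudogene	NA	NA	NA	14560	14680	M5
TRGV1.5	V	TRGV1	5	functional	114	CACAGTGGGTAGAGCCTTTCCGTAGTTGGCACAAAAACG	NA	15080	15200	M5
TRGV3.5	V	TRGV3	5	functional	114	CACGGTGGCCATAACATGTAAACCGTAGACACAAAAACC	NA	15600	15720	M5
TRGV2.17	V	TRGV2	17	pseudogene	NA	NA	NA	16120	16240	M5
TRGV2.18	V	TRGV2	18	functional	114	CACAGTGGAATTGTTCACACGCACTCTTCGATAAAAAGC	NA	16640	16760	M5
TRGV2.19	V	TRGV2	19	functional	114	CACAGTGACTTAGCCCATATGGACAGGGAACCAAAGACC	NA	17160	17280	M5
TRGV2.20	V	TRGV2	20	functional	114	CGCAGTGCTCAGGATACGGGCCAAGCGGCTATAAAACCC	NA	17680	17800	M5
TRGV1.6	V	TRGV1	6	functional	114	CACAGCGGGGCTTGACATCCATACACTGGAACAAAATCC	NA	18200	18320	M6
TRGV3.6	V	TRGV3	6	functional	114	CGCAGTGCGGAAGTACCCGAATCAGACTATACAAAAACC	NA	18720	18840	M6
TRGV2.21	V	TRGV2	21	pseudogene	NA	NA	NA	19240	19360	M6
TRGV2.22	V	TRGV2	22	functional	114	CACAGTGAAAGCATGCAGATGTGCACAACAACAAAATCC	NA	19760	19880	M6
TRGV3.7	V	TRGV3	7	functional	114	CACAGTGCCGGGCGACTCCTTGTCTAAGGAACAAAACCC	NA	20280	20400	M7
TRGJ1	J	NA	NA	functional	39	CACAGTGTACATACAAGTCCCACTGAAGCAACAAAATCC	NA	20800	20860	NA
TRGJ2	J	NA	NA	functional	39	CACAGCGATCACAGTACCGTTGTAGGACCGACAAAAACC	NA	21260	21320	NA
TRGJ3	J	NA	NA	functional	39	CACCGTGTGTAACGAAGTGGCCAGCCATGGACAAAATCC	NA	21720	21780	NA
TRGC	C	NA	NA	functional	NA	NA	NA	22180	22330	NA
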