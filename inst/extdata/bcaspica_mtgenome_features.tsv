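Gene	Strand	Start	End	Category	Anticodon	StartCodon	StopCodon
tRNA-Phe	H	1	72	tRNA	GAA	-	-
12S-rRNA	H	72	1031	rRNA	-	-	-
tRNA-Val	H	1032	1100	tRNA	TAC	-	-
16S-rRNA	H	1101	2668	rRNA	-	-	-
tRNA-Leu2	H	2669	2743	tRNA	TAA	-	-
ND1	H	2749	3705	PCG	-	ATG	TAA
tRNA-Ile	H	3705	3772	tRNA	GAT	-	-
tRNA-Gln	L	3770	3843	tRNA	TTG	-	-
tRNA-Met	H	3844	3911	tRNA	CAT	-	-
ND2	H	3912	4953	PCG	-	ATA	T
tRNA-Trp	H	4954	5020	tRNA	TCA	-	-
tRNA-Ala	L	5028	5095	tRNA	TGC	-	-
tRNA-Asn	L	5096	5168	tRNA	GTT	-	-
tRNA-Cys	L	5200	5266	tRNA	GCA	-	-
tRNA-Tyr	L	5267	5332	tRNA	GTA	-	-
COX1	H	5334	6878	PCG	-	ATG	TAA
tRNA-Ser2	L	6882	6950	tRNA	TGA	-	-
tRNA-Asp	H	6958	7024	tRNA	GTC	-	-
COX2	H	7025	7708	PCG	-	ATG	TAA
tRNA-Lys	H	7711	7779	tRNA	TTT	-	-
ATP8	H	7780	7983	PCG	-	ATG	TAA
ATP6	H	7941	8621	PCG	-	ATG	TAA
COX3	H	8621	9404	PCG	-	ATG	T
tRNA-Gly	H	9404	9472	tRNA	TCC	-	-
ND3	H	9472	9818	PCG	-	ATA	TA
tRNA-Arg	H	9819	9889	tRNA	TCG	-	-
ND4L	H	9891	10187	PCG	-	ATG	TAA
ND4	H	10181	11558	PCG	-	ATG	T
tRNA-His	H	11559	11627	tRNA	GTG	-	-
tRNA-Ser1	H	11628	11686	tRNA	GCT	-	-
tRNA-Leu1	H	11688	11758	tRNA	TAG	-	-
ND5	H	11759	13579	PCG	-	ATA	TAA
ND6	L	13563	14090	PCG	-	ATG	TAA
tRNA-Glu	L	14091	14158	tRNA	TTC	-	-
Cytb	H	14164	15303	PCG	-	ATG	AGA
tRNA-Thr	H	15304	15375	tRNA	TGT	-	-
tRNA-Pro	L	15373	15441	tRNA	TGG	-	-
D-loop	H	15442	16933	control	-	-	-
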