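section	gene	pair	forward_primer	reverse_primer	product_bp	product_bp_alt	t3_ext	incubation_p0_p7_h	incubation_p14_p22_h	ish_used	rtpcr_used	rtpcr_negative
utr	Ankrd13b	NA	TCCAAGGGCGGAGGCAGGTA	TCAGGGAAGGGAAGAGGAAG	821	NA	26	5	6	yes	no	NA
utr	Cdh4	NA	AAGTCCCAGCACTGATGAAAA	ACACCACCCGAATTGTTTGC	501	NA	26	6	6	yes	no	NA
utr	Elfn1	NA	CCTGCGCAAGAAGGTTCAGTT	CTTGCTTGCTTGCACCAGGC	367	NA	26	6	6	yes	no	NA
utr	Eml1	NA	CACTGTGATTTCTGTTTTGTCTAGC	CAGCCTCCCAAAGGGAG	473	NA	26	6	3	yes	no	NA
utr	Fam19a4	NA	AACTTTATGAACCTTGGAGAATGTG	AAATTGGAGGCAAGATGACT	498	NA	26	6	3	yes	no	NA
utr	Foxp2	NA	CTGTGCTGTTAGTGTAAAGATGTG	TTGCTTTCTAGAGTGTCATAAC	503	NA	26	3	3	yes	no	NA
utr	Gabra1	NA	GTTCTTTTAGTCGTATTCTGTTGGA	GCTTGCAAAATAGATTTGCC	900	NA	26	6	6	yes	no	NA
utr	Grm4	NA	GCCACACAGGCCTTCCTTCC	CTTCGAAACACACTCAAGATTAG	433	NA	26	6	5	yes	no	NA
utr	Hpca	NA	CCTCTCCCTCGTGTCTATCC	GAGCTGGGACAAGAAGTGTTC	443	NA	26	6	3	yes	no	NA
utr	Plppr3	NA	CAGTGCCAGCTCCGACTCTT	TTGCCAGGCTTAGTCCTGGTA	469	NA	26	6	6	yes	no	NA
utr	Mapk10	NA	GTCACAACGCACTCACGAAA	GATCTGTATCTACATCCATCTGAC	364	NA	26	6	5	yes	no	NA
utr	Nptx1	NA	GGGGCTGAGAGCTCACTTGA	CCACTTCGAGCCACGCTC	600	NA	26	6	5	yes	no	NA
utr	Nptx2	NA	TCTCCGTCCCAGAGGCCA	CCAGTTCCCTCAGACGGAAAG	486	NA	26	6	6	yes	no	NA
utr	Ntrk1	NA	ATCGAGTGTATCACGCAGGGC	TATGATGGATGCTGGCCATGAA	328	NA	26	6	5	yes	no	NA
utr	Pcdh20	NA	GACGAGTTTCCTACTTCTTGGG	TTATCGTTGATGTCCAGAAGAAG	511	NA	26	6	9	yes	no	NA
utr	Pick1	NA	ACCACTGTAGGACAGCGAAGG	TTATTCAATACAGGCCCAGCTTC	393	NA	26	6	9	yes	no	NA
utr	Pip5kl1	NA	ACAAGGTGTGTCGAAGTCGAAG	TAAGGGTTGGGGTCAGGGTC	458	NA	26	6	6	yes	no	NA
utr	Pnkd	NA	CTTCACCATCCTCTTCATCACTG	AAGGTGGAAGATAGACTAGCC	360	NA	26	6	6	yes	no	NA
utr	Rims1	NA	CACCCTCCTCTGGAGTCCAG	TGTGTCTGCAGTTTATACCAATG	500	NA	26	2	3	yes	no	NA
utr	Tmem25	NA	TGCCTGTCCCTGTTGTGACC	GTACAAAACGATGCAGAGCTAC	687	NA	26	6	6	yes	no	NA
utr	Tmem91	NA	CAACAAGGCTTGGGCCAAGG	GGTATCTTTAATTTCTCACATTG	348	NA	26	6	5	yes	no	NA
utr	Tshz2	NA	GCAGAAAGAAAGGGAAATATGTG	CATCACCTATTTGTTCTCTTCG	418	NA	26	6	6	yes	no	NA
utr	Tusc5	NA	CTGGAGATCTCCGAACCTACAT	ATGGAGGATTTCCGTATGGCC	492	NA	26	6	5	yes	no	NA
utr	Pou4f1	NA	TGTGTAGAAGATCCCCTTTGG	GCACAGAAATGGTTCTGATG	519	NA	26	3	3	yes	no	NA
transcript_specific	Clcc1	pr.1+pr.9	CACAGCTGCGGGCCGAGCCT	GAGATTTCCTCATCGTTCCT	208	NA	26	NA	NA	no	yes	no
transcript_specific	Clcc1	pr.2+pr.9	AGTCCGCTCGGGACTCCAGC	TGAGATTTCCTCATCGTTCCT	181	252	26	7	7	yes	yes	no
transcript_specific	Clcc1	pr.3+pr.9	TGTTTGAGGTAGGCGGCTCG	CTGAGATTTCCTCATCGTTCCT	220	NA	26	NA	NA	no	yes	no
transcript_specific	Clcc1	pr.4+pr.9	TCGGCGTCTTCCGCGGCC	CTGAGATTTCCTCATCGTTCCT	203	NA	26	NA	NA	no	yes	no
transcript_specific	Clcc1	pr.5+pr.9	TCCCTCTGAAAGAGCAGGCAG	CTGAGATTTCCTCATCGTTCCT	172	NA	26	NA	NA	no	yes	no
transcript_specific	Clcc1	pr.6+pr.9	TGAGTGGGCGCTCTTCGGTG	CTGAGATTTCCTCATCGTTCCT	293	NA	26	NA	NA	no	yes	yes
transcript_specific	Clcc1	pr.7+pr.9	CGTTTCCAGGATACACCGAGA	CTGAGATTTCCTCATCGTTCCT	300	NA	26	NA	NA	no	yes	no
transcript_specific	Clcc1	pr.2+pr.8	AGTCCGCTCGGGACTCCAGC	GGGTTAAGGGAAGTCAAATTC	199	270	26	NA	NA	no	yes	yes
transcript_specific	Clcc1	pr.7+pr.8	CGTTTCCAGGATACACCGAGA	CGGGTTAAGGGAAGTCAAATTC	159	NA	26	4	3	yes	no	NA
transcript_specific	Clcc1	pr.10+pr.11	GTGAGGTCTGGAACATCAGAG	CATAAACACATTATATGGATCTA	432	NA	26	NA	NA	no	yes	no
transcript_specific	Pnkd	pr.1+pr.2	TGGGACCCGAACATGGCGGG	GCTAGCCCCACGGCTTTC	246	NA	26	2	3	yes	yes	no
transcript_specific	Pnkd	pr.3+pr.4	TGTGGTATCCTCTTCTTCGTCC	TCCTTCCACGGTGTGGAAG	289	NA	26	2	3	yes	yes	yes
transcript_specific	Pnkd	pr.5+pr.6	CCCAGCATGGCTTGGCAGGC	CGATTCGGAAGAGCAGCCG	167	NA	26	2	3	yes	yes	no
transcript_specific	Pnkd	pr.5+pr.7	CCCAGCATGGCTTGGCAGG	ATTGAAGAGGCGGGGCTGAG	282	NA	26	NA	NA	no	yes	no
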