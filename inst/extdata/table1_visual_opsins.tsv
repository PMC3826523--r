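# Visual opsin gene repertoires of 13 vertebrate species: published
# chromosome/linkage-group assignments and Mb positions (assemblies GRCh37,
# NCBIM37, MonDom5, WASHUC2, AnoCar2.0, JGI_4.2, LatCha1, LepOcu1, Zv9,
# BROADS1, MEDAKA1, TETRAODON8). Mb positions are stored as 0-based point
# anchors (end = start + 1); genes without an assembly placement sit on
# "unmapped" at 0. has_introns is FALSE for the intron-less (retrotransposed)
# rhodopsin genes of the neopterygian fishes.
species	locus_id	family	subtype	chromosome	start	end	strand	has_introns
human	Hsa_OPN1LW	opsin	LWS	X	153410000	153410001	?	TRUE
human	Hsa_OPN1MW2	opsin	LWS	X	153490000	153490001	?	TRUE
human	Hsa_OPN1MW	opsin	LWS	X	153450000	153450001	?	TRUE
human	Hsa_RHO	opsin	RH1	3	129250000	129250001	?	TRUE
human	Hsa_OPN1SW	opsin	SWS1	7	128410000	128410001	?	TRUE
mouse	Mmu_Opn1mw	opsin	LWS	X	71370000	71370001	?	TRUE
mouse	Mmu_Rho	opsin	RH1	6	115880000	115880001	?	TRUE
mouse	Mmu_Opn1sw	opsin	SWS1	6	29330000	29330001	?	TRUE
opossum	Mdo_LWS	opsin	LWS	X	14660000	14660001	?	TRUE
opossum	Mdo_RH1	opsin	RH1	6	246610000	246610001	?	TRUE
opossum	Mdo_SWS1	opsin	SWS1	8	188610000	188610001	?	TRUE
chicken	Gga_LWS	opsin	LWS	unmapped	0	1	?	TRUE
chicken	Gga_RH1	opsin	RH1	12	20160000	20160001	?	TRUE
chicken	Gga_RH2	opsin	RH2	26	4380000	4380001	?	TRUE
chicken	Gga_SWS1	opsin	SWS1	unmapped	0	1	?	TRUE
chicken	Gga_SWS2	opsin	SWS2	unmapped	0	1	?	TRUE
anole	Aca_LWS	opsin	LWS	2	88660000	88660001	?	TRUE
anole	Aca_RH1	opsin	RH1	GL343273.1	640000	640001	?	TRUE
anole	Aca_RH2	opsin	RH2	4	122810000	122810001	?	TRUE
anole	Aca_SWS1	opsin	SWS1	GL343828.1	110000	110001	?	TRUE
anole	Aca_SWS2	opsin	SWS2	2	88630000	88630001	?	TRUE
frog	Xtr_opn1lw	opsin	LWS	GL172911.1	210000	210001	?	TRUE
frog	Xtr_rho	opsin	RH1	GL172832.1	1640000	1640001	?	TRUE
frog	Xtr_opn1sw	opsin	SWS1	GL173116.1	610000	610001	?	TRUE
frog	Xtr_SWS2	opsin	SWS2	GL172911.1	220000	220001	?	TRUE
coelacanth	Lch_RH1	opsin	RH1	JH126975.1	800000	800001	?	TRUE
coelacanth	Lch_RH2	opsin	RH2	JH126819.1	1630000	1630001	?	TRUE
coelacanth	Lch_SWS2	opsin	SWS2	JH127263.1	540000	540001	?	TRUE
gar	Loc_LWS	opsin	LWS	LG1	2610000	2610001	?	TRUE
gar	Loc_RH1-1	opsin	RH1	LG5	40450000	40450001	?	TRUE
gar	Loc_RH1-2	opsin	RH1	LG5	23740000	23740001	?	FALSE
gar	Loc_RH2	opsin	RH2	LG3	36550000	36550001	?	TRUE
gar	Loc_SWS1-1	opsin	SWS1	LG8	10390000	10390001	?	TRUE
gar	Loc_SWS1-2	opsin	SWS1	LG8	10400000	10400001	?	TRUE
gar	Loc_SWS2	opsin	SWS2	LG1	2620000	2620001	?	TRUE
zebrafish	Dre_opn1lw1	opsin	LWS	11	26410000	26410001	?	TRUE
zebrafish	Dre_opn1lw2	opsin	LWS	11	26410000	26410001	?	TRUE
zebrafish	Dre_exorh	opsin	RH1	Zv9_NA986	130	131	?	TRUE
zebrafish	Dre_rho	opsin	RH1	8	55710000	55710001	?	FALSE
zebrafish	Dre_rhol	opsin	RH1	11	19520000	19520001	?	FALSE
zebrafish	Dre_opn1mw1	opsin	RH2	6	41110000	41110001	?	TRUE
zebrafish	Dre_opn1mw2	opsin	RH2	6	41120000	41120001	?	TRUE
zebrafish	Dre_opn1mw3	opsin	RH2	6	41120000	41120001	?	TRUE
zebrafish	Dre_opn1mw4	opsin	RH2	6	41130000	41130001	?	TRUE
zebrafish	Dre_opn1sw1	opsin	SWS1	4	12640000	12640001	?	TRUE
zebrafish	Dre_opn1sw2	opsin	SWS2	11	26410000	26410001	?	TRUE
stickleback	Gac_LWS	opsin	LWS	XVII	10630000	10630001	?	TRUE
stickleback	Gac_RH1-1	opsin	RH1	XII	1180000	1180001	?	TRUE
stickleback	Gac_RH1-2	opsin	RH1	XII	810000	810001	?	FALSE
stickleback	Gac_RH2-1	opsin	RH2	scaffold_27	4150000	4150001	?	TRUE
stickleback	Gac_RH2-2	opsin	RH2	scaffold_27	4160000	4160001	?	TRUE
stickleback	Gac_SWS1	opsin	SWS1	scaffold_90	460000	460001	?	TRUE
stickleback	Gac_SWS2	opsin	SWS2	XVII	10620000	10620001	?	TRUE
medaka	Ola_LWS-1	opsin	LWS	5	27020000	27020001	?	TRUE
medaka	Ola_LWS-2	opsin	LWS	5	27010000	27010001	?	TRUE
medaka	Ola_RH1-1	opsin	RH1	7	17430000	17430001	?	TRUE
medaka	Ola_RH1-2	opsin	RH1	7	17100000	17100001	?	FALSE
medaka	Ola_RH2-1	opsin	RH2	ultracontig_62	1610000	1610001	?	TRUE
medaka	Ola_RH2-2	opsin	RH2	ultracontig_62	1620000	1620001	?	TRUE
medaka	Ola_RH2-3	opsin	RH2	ultracontig_62	1620000	1620001	?	TRUE
medaka	Ola_SWS1	opsin	SWS1	scaffold_1021	40000	40001	?	TRUE
medaka	Ola_SWS2-1	opsin	SWS2	5	27010000	27010001	?	TRUE
medaka	Ola_SWS2-2	opsin	SWS2	5	27000000	27000001	?	TRUE
pufferfish	Tni_LWS	opsin	LWS	11	10120000	10120001	?	TRUE
pufferfish	Tni_RH1-1	opsin	RH1	9	6680000	6680001	?	TRUE
pufferfish	Tni_RH1-2	opsin	RH1	9	6480000	6480001	?	FALSE
pufferfish	Tni_RH2	opsin	RH2	11	5970000	5970001	?	TRUE
pufferfish	Tni_SWS2	opsin	SWS2	11	10120000	10120001	?	TRUE
lamprey	Gau_Lws	opsin	LWS	unmapped	0	1	?	TRUE
lamprey	Gau_RhA	opsin	RH1	unmapped	0	1	?	TRUE
lamprey	Gau_RhB	opsin	RH2	unmapped	0	1	?	TRUE
lamprey	Gau_Sws1	opsin	SWS1	unmapped	0	1	?	TRUE
lamprey	Gau_Sws2	opsin	SWS2	unmapped	0	1	?	TRUE
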