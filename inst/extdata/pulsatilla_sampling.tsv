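species	sample_id	group	matK	rbcL	trnH-psbA	ITS
Pulsatilla_alba	101	ingroup	1	1	1	1
Pulsatilla_alpina	104	ingroup	1	1	1	1
Pulsatilla_ambigua	107	ingroup	1	1	1	1
Pulsatilla_ambigua	108	ingroup	1	1	1	1
Pulsatilla_ambigua	109	ingroup	1	1	1	1
Pulsatilla_ambigua	175	ingroup	1	1	1	1
Pulsatilla_ambigua	189	ingroup	1	1	1	1
Pulsatilla_camanella	111	ingroup	1	1	1	1
Pulsatilla_camanella	112	ingroup	1	1	1	1
Pulsatilla_camanella	113	ingroup	1	1	1	1
Pulsatilla_camanella	114	ingroup	1	1	1	1
Pulsatilla_cernua	115	ingroup	1	1	1	1
Pulsatilla_cernua	116	ingroup	1	1	1	1
Pulsatilla_cernua	176	ingroup	1	1	1	1
Pulsatilla_cernua	177	ingroup	1	1	1	1
Pulsatilla_cernua	190	ingroup	1	1	1	1
Pulsatilla_chinensis	119	ingroup	1	1	1	1
Pulsatilla_chinensis	121	ingroup	1	1	1	1
Pulsatilla_chinensis	122	ingroup	1	1	1	1
Pulsatilla_chinensis	178	ingroup	1	1	1	1
Pulsatilla_dahurica	128	ingroup	1	1	1	1
Pulsatilla_dahurica	129	ingroup	1	1	1	1
Pulsatilla_dahurica	130	ingroup	1	1	1	1
Pulsatilla_dahurica	131	ingroup	1	1	1	1
Pulsatilla_dahurica	174	ingroup	1	1	1	1
Pulsatilla_grandis	132	ingroup	1	1	1	1
Pulsatilla_hirsutissima	133	ingroup	1	1	1	1
Pulsatilla_kostyczewii	135	ingroup	1	1	1	1
Pulsatilla_latifolia	136	ingroup	1	1	1	1
Pulsatilla_ludoviciana	137	ingroup	1	1	1	1
Pulsatilla_occidentalis	145	ingroup	1	1	1	1
Pulsatilla_patens_subsp_multifida	146	ingroup	1	1	1	1
Pulsatilla_patens_subsp_multifida	147	ingroup	1	1	1	1
Pulsatilla_patens_subsp_multifida	179	ingroup	1	1	1	1
Pulsatilla_patens_subsp_multifida	180	ingroup	1	1	1	1
Pulsatilla_patens	148	ingroup	1	1	1	1
Pulsatilla_patens	149	ingroup	1	1	1	1
Pulsatilla_patens	150	ingroup	1	1	1	1
Pulsatilla_patens	151	ingroup	1	1	1	1
Pulsatilla_sukaczevii	181	ingroup	1	1	1	1
Pulsatilla_sukaczevii	182	ingroup	-	-	1	1
Pulsatilla_sukaczevii	187	ingroup	-	-	1	1
Pulsatilla_sukaczevii	188	ingroup	1	1	1	1
Pulsatilla_tenuiloba	159	ingroup	1	1	1	1
Pulsatilla_tenuiloba	160	ingroup	1	1	1	1
Pulsatilla_tenuiloba	183	ingroup	1	1	1	1
Pulsatilla_tenuiloba	184	ingroup	1	1	1	1
Pulsatilla_turczaninovii	161	ingroup	1	1	1	1
Pulsatilla_turczaninovii	162	ingroup	1	1	1	1
Pulsatilla_turczaninovii	185	ingroup	1	1	1	1
Pulsatilla_turczaninovii	186	ingroup	1	1	1	1
Pulsatilla_vulgaris	166	ingroup	1	1	1	1
Anemone_reflexa	167	outgroup	1	1	1	1
Anemone_vitifolia	169	outgroup	1	1	1	1
Anemone_demissa	168	outgroup	1	1	1	-
Clematis_hexapetala	170	outgroup	1	1	1	1
Clematis_tangutica	171	outgroup	1	1	1	1
Hepatica_nobilis	172	outgroup	1	1	1	-
Anemoclema_glaucifolium	173	outgroup	1	1	1	1
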