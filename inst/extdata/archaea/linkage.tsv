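taxon	copy_a	copy_b	gap_orfs
Picrophilus	CoxAC.eury1	CoxB.eury1	1
Ferroplasma	CoxAC.eury1	CoxB.eury1	1
Halobacterium	CoxA1.halo1	CoxB1.halo1	0
Halorubrum	CoxA2.halo2	CoxB2.halo2	0
Halobacterium	CoxA3.halo3	CoxB3.halo3	0
Caldivirga	CoxA.cald	CoxB.cald	0
Pyrobaculum_aerophilum	CoxA.pyro	PoxH.pyro	0
Pyrobaculum_aerophilum	CoxAC.pt	PoxB.pt	0
Aeropyrum	CoxA.aero	PoxH.aero	0
Aeropyrum	CoxAC.aero	PoxB.aero	0
Sulfolobus_tokodaii	SoxB.sulf	SoxA.sulf	0
Sulfolobus_solfataricus	SoxM.sulf	SoxH.sulf	0
Thermococcus_gammatolerans	QoxA.tc	QoxB.tc	0
Halobacterium	QoxA.hb	QoxB.hb	0
Methanosarcina_acetivorans	QoxA.ms	QoxB.ms	0
Pyrobaculum_aerophilum	QoxA.th1	QoxA.th2	0
Hyperthermus	QoxA.ha1	QoxA.ha2	0
Archaeoglobus_fulgidus	DsrA.a1	DsrB.a1	0
Caldivirga	DsrA.a2	DsrB.a2	0
Haloarcula	SseA.hb1	SseA.hb2	0
Ferroglobus	NarG.f1	NarH.f1	0
Haloarcula	NarG.h1	NarH.h1	0
Aeropyrum	NarG.a1	NarH.a1	0
Pyrobaculum_aerophilum	NarG.p1	NarH.p1	0
Sulfolobus_islandicus_M1425	NarG.s1	NarH.s1	0
Metallosphaera_yellowstonensis	NarG.m1	NarH.m1	0
Vulcanisaeta_distributa	NarG.v1	NarH.v1	0
Methanococcus_maripaludis	NifH.c1	NifD.c1	0
Methanococcus_maripaludis	NifD.c1	NifE.c1	0
Methanothermobacter	NifH.c2	NifD.c2	0
Methanothermobacter	NifD.c2	NifE.c2	0
Methanospirillum	NifH.c3	NifD.c3	0
Methanospirillum	NifD.c3	NifE.c3	0
Methanosarcina_barkeri	NifH.c4	NifD.c4	0
Methanosarcina_barkeri	NifD.c4	NifE.c4	0
Thermococcus_kodakarensis	ChiA.t1	GlmA.t1	0
Sulfolobus_solfataricus	PhOH.sis	CatDO.sis	0
Pyrobaculum_arsenaticum	PhOH.pa	Ed3.pa	0
Sulfolobus_tokodaii	HpaH.su	HpaD.su	0
Pyrobaculum_oguniense	HpaH.po	HpaD.po	0
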