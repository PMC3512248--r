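taxon	cox
Thermofilum	0
Pyrobaculum	1
Thermoproteus	1
Caldivirga	0
Vulcanisaeta	0
Sulfolobus	1
Metallosphaera	1
Acidianus	1
Aeropyrum	1
Ignicoccus	0
Hyperthermus	0
Acidilobus	0
Thermococcus	0
Methanococcus	0
Methanothermobacter	0
Archaeoglobus	0
Ferroglobus	0
Thermoplasma	0
Ferroplasma	1
Picrophilus	1
Methanosarcina	0
Halobacterium	1
Natronomonas	1
Haladaptatus	1
Halorubrum	1
Haloterrigena	1
Natrinema	1
Halopiger	1
Haloarcula	1
Halomicrobium	1
Halorhabdus	1
Halobiforma	1
Haloferax	1
Halogeometricum	1
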