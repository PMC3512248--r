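clade	taxa
Crenarchaeota	Thermofilum,Pyrobaculum,Thermoproteus,Caldivirga,Vulcanisaeta,Sulfolobus,Metallosphaera,Acidianus,Aeropyrum,Ignicoccus,Hyperthermus,Acidilobus,Pyrobaculum_calidifontis,Pyrobaculum_oguniense,Pyrobaculum_sp_1860,Pyrobaculum_aerophilum,Pyrobaculum_arsenaticum,Thermoproteus_uzoniensis,Vulcanisaeta_distributa,Vulcanisaeta_moutnovskia,Sulfolobus_solfataricus,Sulfolobus_islandicus,Sulfolobus_islandicus_M1425,Sulfolobus_islandicus_M1627,Sulfolobus_tokodaii,Sulfolobus_acidocaldarius,Sulfolobus_metallicus,Metallosphaera_yellowstonensis,Desulfurolobus
Euryarchaeota	Thermococcus,Methanococcus,Methanothermobacter,Archaeoglobus,Ferroglobus,Thermoplasma,Ferroplasma,Picrophilus,Methanosarcina,Halobacterium,Natronomonas,Haladaptatus,Halorubrum,Haloterrigena,Natrinema,Halopiger,Haloarcula,Halomicrobium,Halorhabdus,Halobiforma,Haloferax,Halogeometricum,Thermococcus_gammatolerans,Thermococcus_AM4,Thermococcus_kodakarensis,Pyrococcus_furiosus,Methanosarcina_acetivorans,Methanosarcina_barkeri,Methanohalophilus,Methanosaeta,Methanoculleus,Methanospirillum,Methanococcus_maripaludis,Methanococcus_vannielii,Methanococcus_aeolicus,Methanosphaera,Methanoregula,Methanobacterium,Thermoplasma_acidophilum,Thermoplasma_volcanium,Archaeoglobus_fulgidus,Archaeoglobus_profundus
Halobacteriales	Halobacterium,Natronomonas,Haladaptatus,Halorubrum,Haloterrigena,Natrinema,Halopiger,Haloarcula,Halomicrobium,Halorhabdus,Halobiforma,Haloferax,Halogeometricum
Sulfolobales	Sulfolobus,Metallosphaera,Acidianus,Desulfurolobus,Sulfolobus_solfataricus,Sulfolobus_islandicus,Sulfolobus_islandicus_M1425,Sulfolobus_islandicus_M1627,Sulfolobus_tokodaii,Sulfolobus_acidocaldarius,Sulfolobus_metallicus,Metallosphaera_yellowstonensis
Thermoproteales	Thermofilum,Pyrobaculum,Thermoproteus,Caldivirga,Vulcanisaeta,Pyrobaculum_calidifontis,Pyrobaculum_oguniense,Pyrobaculum_sp_1860,Pyrobaculum_aerophilum,Pyrobaculum_arsenaticum,Thermoproteus_uzoniensis,Vulcanisaeta_distributa,Vulcanisaeta_moutnovskia
Thermoplasmatales	Thermoplasma,Ferroplasma,Picrophilus,Thermoplasma_acidophilum,Thermoplasma_volcanium
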