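(((Thermofilum:2.9,((Pyrobaculum:1,Thermoproteus:1):1.2,(Caldivirga:1.7,Vulcanisaeta:1.7):0.5):0.7)Thermoproteales:0.3,((Sulfolobus:1.2,(Metallosphaera:0.8,Acidianus:0.8):0.4)Sulfolobales:1.8,((Aeropyrum:1.9,Ignicoccus:1.9):0.5,(Hyperthermus:1.6,Acidilobus:1.6):0.8)Desulfurococcales:0.6):0.2)Crenarchaeota:0.3,(Thermococcus:3.3,(Methanococcus:3.1,(Methanothermobacter:3,((Archaeoglobus:2,Ferroglobus:2):0.9,((Thermoplasma:1.5,(Ferroplasma:0.8,Picrophilus:0.8):0.7)Thermoplasmatales:1.3,(Methanosarcina:2.6,(Halobacterium:1.8,(Natronomonas:1.5,(Haladaptatus:1.3,((Halorubrum:0.9,(Haloterrigena:0.7,(Natrinema:0.5,Halopiger:0.5):0.2):0.2):0.2,((Haloarcula:0.6,Halomicrobium:0.6):0.35,(Halorhabdus:0.75,(Halobiforma:0.55,(Haloferax:0.35,Halogeometricum:0.35):0.2):0.2):0.2):0.15):0.2):0.2):0.3)Halobacteriales:0.8):0.2):0.1):0.1):0.1):0.2)Euryarchaeota:0.2);
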