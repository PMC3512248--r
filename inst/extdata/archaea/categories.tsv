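gene	category	group
CoxAC	Cytochrome oxidase	Oxygen
CoxA1	Cytochrome oxidase	Oxygen
CoxA2	Cytochrome oxidase	Oxygen
CoxA3	Cytochrome oxidase	Oxygen
CoxA	Cytochrome oxidase	Oxygen
CoxB	Cytochrome oxidase	Oxygen
CoxB1	Cytochrome oxidase	Oxygen
CoxB2	Cytochrome oxidase	Oxygen
CoxB3	Cytochrome oxidase	Oxygen
PoxH	Cytochrome oxidase	Oxygen
PoxB	Cytochrome oxidase	Oxygen
SoxA	Cytochrome oxidase	Oxygen
SoxB	Cytochrome oxidase	Oxygen
SoxH	Cytochrome oxidase	Oxygen
SoxM	Cytochrome oxidase	Oxygen
DoxB	Cytochrome oxidase	Oxygen
FoxA	Cytochrome oxidase	Oxygen
QoxA	Quinol oxidase	Oxygen
QoxB	Quinol oxidase	Oxygen
DsrA	Dissimilatory sulfite reductase (DsrAB)	Sulfur
DsrB	Dissimilatory sulfite reductase (DsrAB)	Sulfur
SseA	Thiosulfate sulfurtransferase (SseA)	Sulfur
SOR	Sulfur oxygenase reductase (SOR)	Sulfur
SreC	Sulfur reductase (SreC)	Sulfur
FCSD	Flavocytochrome c sulfide dehydrogenase (FCSD)	Sulfur
SQO	Sulfide quinone oxidoreductase (SQO)	Sulfur
NarG	Nitrate reductase (NarGH)	Nitrogen
NarH	Nitrate reductase (NarGH)	Nitrogen
NirK	Nitrite reductase (NirK)	Nitrogen
NirS	Nitrite reductase (NirS)	Nitrogen
NorB	Nitric oxide reductase (NorB)	Nitrogen
NosZ	Nitrous oxide reductase (NosZ)	Nitrogen
NifH	Nitrogenase (NifHDE)	Nitrogen
NifD	Nitrogenase (NifHDE)	Nitrogen
NifE	Nitrogenase (NifHDE)	Nitrogen
ChiA	Chitin degradation	Carbon
GlmA	Chitin degradation	Carbon
PhOH	Oxidation of phenolic compounds	Carbon
HpaH	Oxidation of phenolic compounds	Carbon
HpaD	Oxidation of phenolic compounds	Carbon
CatDO	Oxidation of phenolic compounds	Carbon
Ed3	Oxidation of phenolic compounds	Carbon
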