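tca_cycle	Citric acid	cis-Aconitic acid
tca_cycle	cis-Aconitic acid	Isocitric acid
tca_cycle	Isocitric acid	Oxoglutaric acid
tca_cycle	Oxoglutaric acid	Succinyl-CoA
tca_cycle	Succinyl-CoA	Succinic acid
tca_cycle	Succinic acid	Fumaric acid
tca_cycle	Fumaric acid	Malic acid
tca_cycle	Malic acid	Oxaloacetic acid
tca_cycle	Oxaloacetic acid	Citric acid
ala_asp_glu	L-Glutamic acid	L-Glutamine
ala_asp_glu	L-Glutamic acid	Oxoglutaric acid
ala_asp_glu	L-Glutamic acid	GABA
ala_asp_glu	L-Aspartic acid	L-Asparagine
ala_asp_glu	L-Aspartic acid	L-Glutamic acid
ala_asp_glu	L-Alanine	L-Glutamic acid
bile_acid	Cholesterol	7a-Hydroxycholesterol
bile_acid	7a-Hydroxycholesterol	Cholic acid
bile_acid	7a-Hydroxycholesterol	Chenodeoxycholic acid
bile_acid	Cholic acid	Taurocholic acid
bile_acid	Cholic acid	Glycocholic acid
purine	AMP	Cyclic AMP
purine	AMP	Adenosine
purine	Adenosine	Inosine
purine	Inosine	Hypoxanthine
purine	Hypoxanthine	Xanthine
purine	Xanthine	Uric acid
purine	AMP	Guanosine
glycolysis	D-Glucose	Glucose 6-phosphate
glycolysis	Glucose 6-phosphate	Fructose 6-phosphate
glycolysis	Fructose 6-phosphate	Fructose 1,6-bisphosphate
glycolysis	Fructose 1,6-bisphosphate	Glyceraldehyde 3-phosphate
glycolysis	Glyceraldehyde 3-phosphate	3-Phosphoglyceric acid
glycolysis	3-Phosphoglyceric acid	Phosphoenolpyruvic acid
glycolysis	Phosphoenolpyruvic acid	Pyruvic acid
glycolysis	Pyruvic acid	L-Lactic acid
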