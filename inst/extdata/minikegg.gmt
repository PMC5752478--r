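tca_cycle	Citrate cycle (TCA cycle)	Citric acid	cis-Aconitic acid	Isocitric acid	Oxoglutaric acid	Succinyl-CoA	Succinic acid	Fumaric acid	Malic acid	Oxaloacetic acid
ala_asp_glu	Alanine, aspartate and glutamate metabolism	L-Alanine	L-Aspartic acid	L-Asparagine	L-Glutamic acid	L-Glutamine	GABA	Oxoglutaric acid
bile_acid	Primary bile acid biosynthesis	Cholesterol	7a-Hydroxycholesterol	Cholic acid	Chenodeoxycholic acid	Taurocholic acid	Glycocholic acid
purine	Purine metabolism	AMP	Cyclic AMP	Adenosine	Inosine	Hypoxanthine	Xanthine	Uric acid	Guanosine
glycolysis	Glycolysis / Gluconeogenesis	D-Glucose	Glucose 6-phosphate	Fructose 6-phosphate	Fructose 1,6-bisphosphate	Glyceraldehyde 3-phosphate	3-Phosphoglyceric acid	Phosphoenolpyruvic acid	Pyruvic acid	L-Lactic acid
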