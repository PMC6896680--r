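enzyme	rule_id	position	constraint_type	residues
pepsin_pH_gt2	p1_hydrophobic	-1	allowed	FLWY
pepsin_pH_gt2	p1_hydrophobic	-2	forbidden	HKR
pepsin_pH_gt2	p1_hydrophobic	1	forbidden	P
pepsin_pH_gt2	p1prime_hydrophobic	1	allowed	FLWY
pepsin_pH_gt2	p1prime_hydrophobic	-1	forbidden	P
pepsin_pH_gt2	p1prime_hydrophobic	-2	forbidden	HKR
pepsin_pH_gt2	p1prime_hydrophobic	2	forbidden	P
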