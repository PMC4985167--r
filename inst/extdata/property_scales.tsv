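property_name	amino_acid	value
hydrophobicity	A	1.8
hydrophobicity	R	-4.5
hydrophobicity	N	-3.5
hydrophobicity	D	-3.5
hydrophobicity	C	2.5
hydrophobicity	Q	-3.5
hydrophobicity	E	-3.5
hydrophobicity	G	-0.4
hydrophobicity	H	-3.2
hydrophobicity	I	4.5
hydrophobicity	L	3.8
hydrophobicity	K	-3.9
hydrophobicity	M	1.9
hydrophobicity	F	2.8
hydrophobicity	P	-1.6
hydrophobicity	S	-0.8
hydrophobicity	T	-0.7
hydrophobicity	W	-0.9
hydrophobicity	Y	-1.3
hydrophobicity	V	4.2
hydrophilicity	A	-0.5
hydrophilicity	R	3.0
hydrophilicity	N	0.2
hydrophilicity	D	3.0
hydrophilicity	C	-1.0
hydrophilicity	Q	0.2
hydrophilicity	E	3.0
hydrophilicity	G	0.0
hydrophilicity	H	-0.5
hydrophilicity	I	-1.8
hydrophilicity	L	-1.8
hydrophilicity	K	3.0
hydrophilicity	M	-1.3
hydrophilicity	F	-2.5
hydrophilicity	P	0.0
hydrophilicity	S	0.3
hydrophilicity	T	-0.4
hydrophilicity	W	-3.4
hydrophilicity	Y	-2.3
hydrophilicity	V	-1.5
molecular_weight	A	89.09
molecular_weight	R	174.20
molecular_weight	N	132.12
molecular_weight	D	133.10
molecular_weight	C	121.16
molecular_weight	Q	146.15
molecular_weight	E	147.13
molecular_weight	G	75.07
molecular_weight	H	155.16
molecular_weight	I	131.17
molecular_weight	L	131.17
molecular_weight	K	146.19
molecular_weight	M	149.21
molecular_weight	F	165.19
molecular_weight	P	115.13
molecular_weight	S	105.09
molecular_weight	T	119.12
molecular_weight	W	204.23
molecular_weight	Y	181.19
molecular_weight	V	117.15
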