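name	smarts	atom	dCharge	dH
amidine_guanidine	[NX2;+0]=[CX3;!$([CX3][OX2]);!$([CX3][SX2])][NX3;+0]	1	1	1
aliphatic_amine	[NX3;+0;!$([N][a]);!$([N][CX3]=[OX1]);!$([N][CX3]=[SX1]);!$([N][CX3]=[NX2]);!$([N][SX4](=[OX1])(=[OX1]));!$([N][OX1,OX2]);!$([N][NX2,NX3])]	1	1	1
carboxylic_acid	[CX3](=[OX1])[OX2;H1]	3	-1	-1
tetrazole_nh	[nH;$(n1nnnc1),$(n1nncn1)]	1	-1	-1
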