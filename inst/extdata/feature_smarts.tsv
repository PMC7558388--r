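type	smarts	mode	label
DONOR	[#7;!H0]	atom	N-H donor
DONOR	[#8;!H0]	atom	O-H donor
ACCEPTOR	[OX1]	atom	carbonyl/carboxylate O acceptor
ACCEPTOR	[OX2;H1;+0]	atom	hydroxyl O acceptor
ACCEPTOR	[OX2;H0;+0;!$([o])]	atom	ether/ester O acceptor
ACCEPTOR	[nX2;+0]	atom	aromatic N acceptor
ACCEPTOR	[NX1;+0]	atom	nitrile N acceptor
ACCEPTOR	[NX2;+0;!$([NX2]=[OX1])]	atom	imine N acceptor
ACCEPTOR	[NX3;+0;!$([NX3][CX3]=[OX1]);!$([NX3][SX4](=[OX1])(=[OX1]))]	atom	amine N acceptor
AROMATIC	a1aaaa1	centroid	5-membered aromatic ring
AROMATIC	a1aaaaa1	centroid	6-membered aromatic ring
AROMATIC	a1aaaaaa1	centroid	7-membered aromatic ring
HYDROPHOBIC	[C;R]1[C;R][C;R]1	centroid	3-membered carbocycle
HYDROPHOBIC	[C;R]1[C;R][C;R][C;R]1	centroid	4-membered carbocycle
HYDROPHOBIC	[C;R]1[C;R][C;R][C;R][C;R]1	centroid	5-membered carbocycle
HYDROPHOBIC	[C;R]1[C;R][C;R][C;R][C;R][C;R]1	centroid	6-membered carbocycle
HYDROPHOBIC	[C;R]1[C;R][C;R][C;R][C;R][C;R][C;R]1	centroid	7-membered carbocycle
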