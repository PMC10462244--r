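res	atom	types
*	N	H-bond Donor,Amide Nitrogen
*	CA	Aliphatic Carbon
*	C	Aliphatic Carbon
*	O	H-bond Acceptor
*	OXT	H-bond Acceptor,Carboxylate Oxygen,NegativeIonizable
PRO	N	Amide Nitrogen
ALA	CB	Aliphatic Carbon
ARG	CB	Aliphatic Carbon
ARG	CG	Aliphatic Carbon
ARG	CD	Aliphatic Carbon
ARG	CZ	Aliphatic Carbon
ARG	NE	H-bond Donor,Positive Ionizable,Imine Nitrogen
ARG	NH1	H-bond Donor,Positive Ionizable,Amine Nitrogen
ARG	NH2	H-bond Donor,Positive Ionizable,Amine Nitrogen
ASN	CB	Aliphatic Carbon
ASN	CG	Aliphatic Carbon
ASN	OD1	H-bond Acceptor
ASN	ND2	H-bond Donor,Amide Nitrogen
ASP	CB	Aliphatic Carbon
ASP	CG	Aliphatic Carbon
ASP	OD1	H-bond Acceptor,Carboxylate Oxygen,NegativeIonizable
ASP	OD2	H-bond Acceptor,Carboxylate Oxygen,NegativeIonizable
CYS	CB	Aliphatic Carbon
GLN	CB	Aliphatic Carbon
GLN	CG	Aliphatic Carbon
GLN	CD	Aliphatic Carbon
GLN	OE1	H-bond Acceptor
GLN	NE2	H-bond Donor,Amide Nitrogen
GLU	CB	Aliphatic Carbon
GLU	CG	Aliphatic Carbon
GLU	CD	Aliphatic Carbon
GLU	OE1	H-bond Acceptor,Carboxylate Oxygen,NegativeIonizable
GLU	OE2	H-bond Acceptor,Carboxylate Oxygen,NegativeIonizable
HIS	CB	Aliphatic Carbon
HIS	CG	Aromatic,Aromatic Carbon
HIS	CD2	Aromatic,Aromatic Carbon
HIS	CE1	Aromatic,Aromatic Carbon
HIS	ND1	Aromatic,Aromatic Nitrogen,H-bond Acceptor
HIS	NE2	Aromatic,Aromatic Nitrogen,H-bond Donor
ILE	CB	Aliphatic Carbon
ILE	CG1	Aliphatic Carbon
ILE	CG2	Aliphatic Carbon
ILE	CD1	Aliphatic Carbon
LEU	CB	Aliphatic Carbon
LEU	CG	Aliphatic Carbon
LEU	CD1	Aliphatic Carbon
LEU	CD2	Aliphatic Carbon
LYS	CB	Aliphatic Carbon
LYS	CG	Aliphatic Carbon
LYS	CD	Aliphatic Carbon
LYS	CE	Aliphatic Carbon
LYS	NZ	H-bond Donor,Positive Ionizable,Amine Nitrogen
MET	CB	Aliphatic Carbon
MET	CG	Aliphatic Carbon
MET	CE	Aliphatic Carbon
PHE	CB	Aliphatic Carbon
PHE	CG	Aromatic,Aromatic Carbon
PHE	CD1	Aromatic,Aromatic Carbon
PHE	CD2	Aromatic,Aromatic Carbon
PHE	CE1	Aromatic,Aromatic Carbon
PHE	CE2	Aromatic,Aromatic Carbon
PHE	CZ	Aromatic,Aromatic Carbon
PRO	CB	Aliphatic Carbon
PRO	CG	Aliphatic Carbon
PRO	CD	Aliphatic Carbon
SER	CB	Aliphatic Carbon
SER	OG	H-bond Donor,H-bond Acceptor,Alcohol Oxygen
THR	CB	Aliphatic Carbon
THR	OG1	H-bond Donor,H-bond Acceptor,Alcohol Oxygen
THR	CG2	Aliphatic Carbon
TRP	CB	Aliphatic Carbon
TRP	CG	Aromatic,Aromatic Carbon
TRP	CD1	Aromatic,Aromatic Carbon
TRP	CD2	Aromatic,Aromatic Carbon
TRP	NE1	Aromatic,Aromatic Nitrogen,H-bond Donor
TRP	CE2	Aromatic,Aromatic Carbon
TRP	CE3	Aromatic,Aromatic Carbon
TRP	CZ2	Aromatic,Aromatic Carbon
TRP	CZ3	Aromatic,Aromatic Carbon
TRP	CH2	Aromatic,Aromatic Carbon
TYR	CB	Aliphatic Carbon
TYR	CG	Aromatic,Aromatic Carbon
TYR	CD1	Aromatic,Aromatic Carbon
TYR	CD2	Aromatic,Aromatic Carbon
TYR	CE1	Aromatic,Aromatic Carbon
TYR	CE2	Aromatic,Aromatic Carbon
TYR	CZ	Aromatic,Aromatic Carbon
TYR	OH	H-bond Donor,H-bond Acceptor,Alcohol Oxygen
VAL	CB	Aliphatic Carbon
VAL	CG1	Aliphatic Carbon
VAL	CG2	Aliphatic Carbon
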