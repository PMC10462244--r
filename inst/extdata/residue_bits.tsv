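res	size1	size2	size3	hyd1	hyd2	hyd3	hba	hbd	pos	neg	aro
ALA	0	0	0	1	0	0	0	0	0	0	0
ARG	1	1	0	0	0	0	0	1	1	0	0
ASN	1	0	0	0	0	0	1	1	0	0	0
ASP	1	0	0	0	0	0	1	0	0	1	0
CYS	1	0	0	1	1	0	0	0	0	0	0
GLN	1	1	0	0	0	0	1	1	0	0	0
GLU	1	1	0	0	0	0	1	0	0	1	0
GLY	0	0	0	0	0	0	0	0	0	0	0
HIS	1	1	0	0	0	0	1	1	0	0	1
ILE	1	0	0	1	1	1	0	0	0	0	0
LEU	1	0	0	1	1	0	0	0	0	0	0
LYS	1	1	0	0	0	0	0	1	1	0	0
MET	1	0	0	1	1	0	0	0	0	0	0
PHE	1	1	0	1	1	0	0	0	0	0	1
PRO	1	0	0	1	0	0	0	0	0	0	0
SER	1	0	0	0	0	0	1	1	0	0	0
THR	1	0	0	1	0	0	1	1	0	0	0
TRP	1	1	1	1	1	1	0	1	0	0	1
TYR	1	1	1	1	0	0	1	1	0	0	1
VAL	1	0	0	1	1	0	0	0	0	0	0
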