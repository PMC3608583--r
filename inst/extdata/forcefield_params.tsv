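residue	atom	element	charge	epsilon	rmin_half	radius	mass
ALA	N	N	-0.47	0.2	1.85	1.55	14.007
ALA	H	H	0.31	0.046	0.2245	0.85	1.008
ALA	CA	C	0.16	0.086	1.9924	1.7	12.011
ALA	C	C	0.51	0.086	1.9924	1.7	12.011
ALA	O	O	-0.51	0.21	1.7	1.5	15.999
ALA	CB	C	0	0.086	1.9924	1.7	12.011
ARG	N	N	-0.47	0.2	1.85	1.55	14.007
ARG	H	H	0.31	0.046	0.2245	0.85	1.008
ARG	CA	C	0.16	0.086	1.9924	1.7	12.011
ARG	C	C	0.51	0.086	1.9924	1.7	12.011
ARG	O	O	-0.51	0.21	1.7	1.5	15.999
ARG	CB	C	0	0.086	1.9924	1.7	12.011
ARG	CG	C	0	0.086	1.9924	1.7	12.011
ARG	CD	C	0.38	0.086	1.9924	1.7	12.011
ARG	NE	N	-0.7	0.2	1.85	1.55	14.007
ARG	HE	H	0.44	0.046	0.2245	0.85	1.008
ARG	CZ	C	0.64	0.086	1.9924	1.7	12.011
ARG	NH1	N	-0.8	0.2	1.85	1.55	14.007
ARG	HH11	H	0.46	0.046	0.2245	0.85	1.008
ARG	HH12	H	0.46	0.046	0.2245	0.85	1.008
ARG	NH2	N	-0.8	0.2	1.85	1.55	14.007
ARG	HH21	H	0.46	0.046	0.2245	0.85	1.008
ARG	HH22	H	0.46	0.046	0.2245	0.85	1.008
ASN	N	N	-0.47	0.2	1.85	1.55	14.007
ASN	H	H	0.31	0.046	0.2245	0.85	1.008
ASN	CA	C	0.16	0.086	1.9924	1.7	12.011
ASN	C	C	0.51	0.086	1.9924	1.7	12.011
ASN	O	O	-0.51	0.21	1.7	1.5	15.999
ASN	CB	C	0	0.086	1.9924	1.7	12.011
ASN	CG	C	0.55	0.086	1.9924	1.7	12.011
ASN	OD1	O	-0.55	0.21	1.7	1.5	15.999
ASN	ND2	N	-0.62	0.2	1.85	1.55	14.007
ASN	HD21	H	0.31	0.046	0.2245	0.85	1.008
ASN	HD22	H	0.31	0.046	0.2245	0.85	1.008
ASP	N	N	-0.47	0.2	1.85	1.55	14.007
ASP	H	H	0.31	0.046	0.2245	0.85	1.008
ASP	CA	C	0.16	0.086	1.9924	1.7	12.011
ASP	C	C	0.51	0.086	1.9924	1.7	12.011
ASP	O	O	-0.51	0.21	1.7	1.5	15.999
ASP	CB	C	-0.1	0.086	1.9924	1.7	12.011
ASP	CG	C	0.62	0.086	1.9924	1.7	12.011
ASP	OD1	O	-0.76	0.21	1.7	1.5	15.999
ASP	OD2	O	-0.76	0.21	1.7	1.5	15.999
CYS	N	N	-0.47	0.2	1.85	1.55	14.007
CYS	H	H	0.31	0.046	0.2245	0.85	1.008
CYS	CA	C	0.16	0.086	1.9924	1.7	12.011
CYS	C	C	0.51	0.086	1.9924	1.7	12.011
CYS	O	O	-0.51	0.21	1.7	1.5	15.999
CYS	CB	C	0.07	0.086	1.9924	1.7	12.011
CYS	SG	S	-0.23	0.45	2	1.8	32.06
CYS	HG	H	0.16	0.046	0.2245	0.85	1.008
GLN	N	N	-0.47	0.2	1.85	1.55	14.007
GLN	H	H	0.31	0.046	0.2245	0.85	1.008
GLN	CA	C	0.16	0.086	1.9924	1.7	12.011
GLN	C	C	0.51	0.086	1.9924	1.7	12.011
GLN	O	O	-0.51	0.21	1.7	1.5	15.999
GLN	CB	C	0	0.086	1.9924	1.7	12.011
GLN	CG	C	0	0.086	1.9924	1.7	12.011
GLN	CD	C	0.55	0.086	1.9924	1.7	12.011
GLN	OE1	O	-0.55	0.21	1.7	1.5	15.999
GLN	NE2	N	-0.62	0.2	1.85	1.55	14.007
GLN	HE21	H	0.31	0.046	0.2245	0.85	1.008
GLN	HE22	H	0.31	0.046	0.2245	0.85	1.008
GLU	N	N	-0.47	0.2	1.85	1.55	14.007
GLU	H	H	0.31	0.046	0.2245	0.85	1.008
GLU	CA	C	0.16	0.086	1.9924	1.7	12.011
GLU	C	C	0.51	0.086	1.9924	1.7	12.011
GLU	O	O	-0.51	0.21	1.7	1.5	15.999
GLU	CB	C	0	0.086	1.9924	1.7	12.011
GLU	CG	C	-0.1	0.086	1.9924	1.7	12.011
GLU	CD	C	0.62	0.086	1.9924	1.7	12.011
GLU	OE1	O	-0.76	0.21	1.7	1.5	15.999
GLU	OE2	O	-0.76	0.21	1.7	1.5	15.999
GLY	N	N	-0.47	0.2	1.85	1.55	14.007
GLY	H	H	0.31	0.046	0.2245	0.85	1.008
GLY	CA	C	0.16	0.086	1.9924	1.7	12.011
GLY	C	C	0.51	0.086	1.9924	1.7	12.011
GLY	O	O	-0.51	0.21	1.7	1.5	15.999
HIS	N	N	-0.47	0.2	1.85	1.55	14.007
HIS	H	H	0.31	0.046	0.2245	0.85	1.008
HIS	CA	C	0.16	0.086	1.9924	1.7	12.011
HIS	C	C	0.51	0.086	1.9924	1.7	12.011
HIS	O	O	-0.51	0.21	1.7	1.5	15.999
HIS	CB	C	0	0.086	1.9924	1.7	12.011
HIS	CG	C	0	0.086	1.9924	1.7	12.011
HIS	ND1	N	-0.4	0.2	1.85	1.55	14.007
HIS	HD1	H	0.4	0.046	0.2245	0.85	1.008
HIS	CD2	C	0	0.086	1.9924	1.7	12.011
HIS	CE1	C	0.25	0.086	1.9924	1.7	12.011
HIS	NE2	N	-0.25	0.2	1.85	1.55	14.007
ILE	N	N	-0.47	0.2	1.85	1.55	14.007
ILE	H	H	0.31	0.046	0.2245	0.85	1.008
ILE	CA	C	0.16	0.086	1.9924	1.7	12.011
ILE	C	C	0.51	0.086	1.9924	1.7	12.011
ILE	O	O	-0.51	0.21	1.7	1.5	15.999
ILE	CB	C	0	0.086	1.9924	1.7	12.011
ILE	CG1	C	0	0.086	1.9924	1.7	12.011
ILE	CG2	C	0	0.086	1.9924	1.7	12.011
ILE	CD1	C	0	0.086	1.9924	1.7	12.011
LEU	N	N	-0.47	0.2	1.85	1.55	14.007
LEU	H	H	0.31	0.046	0.2245	0.85	1.008
LEU	CA	C	0.16	0.086	1.9924	1.7	12.011
LEU	C	C	0.51	0.086	1.9924	1.7	12.011
LEU	O	O	-0.51	0.21	1.7	1.5	15.999
LEU	CB	C	0	0.086	1.9924	1.7	12.011
LEU	CG	C	0	0.086	1.9924	1.7	12.011
LEU	CD1	C	0	0.086	1.9924	1.7	12.011
LEU	CD2	C	0	0.086	1.9924	1.7	12.011
LYS	N	N	-0.47	0.2	1.85	1.55	14.007
LYS	H	H	0.31	0.046	0.2245	0.85	1.008
LYS	CA	C	0.16	0.086	1.9924	1.7	12.011
LYS	C	C	0.51	0.086	1.9924	1.7	12.011
LYS	O	O	-0.51	0.21	1.7	1.5	15.999
LYS	CB	C	0	0.086	1.9924	1.7	12.011
LYS	CG	C	0	0.086	1.9924	1.7	12.011
LYS	CD	C	0	0.086	1.9924	1.7	12.011
LYS	CE	C	0.25	0.086	1.9924	1.7	12.011
LYS	NZ	N	-0.3	0.2	1.85	1.55	14.007
LYS	HZ1	H	0.35	0.046	0.2245	0.85	1.008
LYS	HZ2	H	0.35	0.046	0.2245	0.85	1.008
LYS	HZ3	H	0.35	0.046	0.2245	0.85	1.008
MET	N	N	-0.47	0.2	1.85	1.55	14.007
MET	H	H	0.31	0.046	0.2245	0.85	1.008
MET	CA	C	0.16	0.086	1.9924	1.7	12.011
MET	C	C	0.51	0.086	1.9924	1.7	12.011
MET	O	O	-0.51	0.21	1.7	1.5	15.999
MET	CB	C	0	0.086	1.9924	1.7	12.011
MET	CG	C	0.06	0.086	1.9924	1.7	12.011
MET	SD	S	-0.12	0.45	2	1.8	32.06
MET	CE	C	0.06	0.086	1.9924	1.7	12.011
PHE	N	N	-0.47	0.2	1.85	1.55	14.007
PHE	H	H	0.31	0.046	0.2245	0.85	1.008
PHE	CA	C	0.16	0.086	1.9924	1.7	12.011
PHE	C	C	0.51	0.086	1.9924	1.7	12.011
PHE	O	O	-0.51	0.21	1.7	1.5	15.999
PHE	CB	C	0	0.086	1.9924	1.7	12.011
PHE	CG	C	0	0.086	1.9924	1.7	12.011
PHE	CD1	C	0	0.086	1.9924	1.7	12.011
PHE	CD2	C	0	0.086	1.9924	1.7	12.011
PHE	CE1	C	0	0.086	1.9924	1.7	12.011
PHE	CE2	C	0	0.086	1.9924	1.7	12.011
PHE	CZ	C	0	0.086	1.9924	1.7	12.011
PRO	N	N	-0.16	0.2	1.85	1.55	14.007
PRO	CA	C	0.16	0.086	1.9924	1.7	12.011
PRO	C	C	0.51	0.086	1.9924	1.7	12.011
PRO	O	O	-0.51	0.21	1.7	1.5	15.999
PRO	CB	C	0	0.086	1.9924	1.7	12.011
PRO	CG	C	0	0.086	1.9924	1.7	12.011
PRO	CD	C	0	0.086	1.9924	1.7	12.011
SER	N	N	-0.47	0.2	1.85	1.55	14.007
SER	H	H	0.31	0.046	0.2245	0.85	1.008
SER	CA	C	0.16	0.086	1.9924	1.7	12.011
SER	C	C	0.51	0.086	1.9924	1.7	12.011
SER	O	O	-0.51	0.21	1.7	1.5	15.999
SER	CB	C	0.05	0.086	1.9924	1.7	12.011
SER	OG	O	-0.48	0.21	1.7	1.5	15.999
SER	HG	H	0.43	0.046	0.2245	0.85	1.008
THR	N	N	-0.47	0.2	1.85	1.55	14.007
THR	H	H	0.31	0.046	0.2245	0.85	1.008
THR	CA	C	0.16	0.086	1.9924	1.7	12.011
THR	C	C	0.51	0.086	1.9924	1.7	12.011
THR	O	O	-0.51	0.21	1.7	1.5	15.999
THR	CB	C	0.05	0.086	1.9924	1.7	12.011
THR	OG1	O	-0.48	0.21	1.7	1.5	15.999
THR	HG1	H	0.43	0.046	0.2245	0.85	1.008
THR	CG2	C	0	0.086	1.9924	1.7	12.011
TRP	N	N	-0.47	0.2	1.85	1.55	14.007
TRP	H	H	0.31	0.046	0.2245	0.85	1.008
TRP	CA	C	0.16	0.086	1.9924	1.7	12.011
TRP	C	C	0.51	0.086	1.9924	1.7	12.011
TRP	O	O	-0.51	0.21	1.7	1.5	15.999
TRP	CB	C	0	0.086	1.9924	1.7	12.011
TRP	CG	C	0	0.086	1.9924	1.7	12.011
TRP	CD1	C	0.06	0.086	1.9924	1.7	12.011
TRP	CD2	C	0	0.086	1.9924	1.7	12.011
TRP	NE1	N	-0.38	0.2	1.85	1.55	14.007
TRP	HE1	H	0.32	0.046	0.2245	0.85	1.008
TRP	CE2	C	0	0.086	1.9924	1.7	12.011
TRP	CE3	C	0	0.086	1.9924	1.7	12.011
TRP	CZ2	C	0	0.086	1.9924	1.7	12.011
TRP	CZ3	C	0	0.086	1.9924	1.7	12.011
TRP	CH2	C	0	0.086	1.9924	1.7	12.011
TYR	N	N	-0.47	0.2	1.85	1.55	14.007
TYR	H	H	0.31	0.046	0.2245	0.85	1.008
TYR	CA	C	0.16	0.086	1.9924	1.7	12.011
TYR	C	C	0.51	0.086	1.9924	1.7	12.011
TYR	O	O	-0.51	0.21	1.7	1.5	15.999
TYR	CB	C	0	0.086	1.9924	1.7	12.011
TYR	CG	C	0	0.086	1.9924	1.7	12.011
TYR	CD1	C	0	0.086	1.9924	1.7	12.011
TYR	CD2	C	0	0.086	1.9924	1.7	12.011
TYR	CE1	C	0	0.086	1.9924	1.7	12.011
TYR	CE2	C	0	0.086	1.9924	1.7	12.011
TYR	CZ	C	0.11	0.086	1.9924	1.7	12.011
TYR	OH	O	-0.54	0.21	1.7	1.5	15.999
TYR	HH	H	0.43	0.046	0.2245	0.85	1.008
VAL	N	N	-0.47	0.2	1.85	1.55	14.007
VAL	H	H	0.31	0.046	0.2245	0.85	1.008
VAL	CA	C	0.16	0.086	1.9924	1.7	12.011
VAL	C	C	0.51	0.086	1.9924	1.7	12.011
VAL	O	O	-0.51	0.21	1.7	1.5	15.999
VAL	CB	C	0	0.086	1.9924	1.7	12.011
VAL	CG1	C	0	0.086	1.9924	1.7	12.011
VAL	CG2	C	0	0.086	1.9924	1.7	12.011
HOH	O	O	-0.834	0.21	1.7	1.5	15.999
HOH	H1	H	0.417	0.046	0.2245	0.85	1.008
HOH	H2	H	0.417	0.046	0.2245	0.85	1.008
WAT	O	O	-0.834	0.21	1.7	1.5	15.999
WAT	H1	H	0.417	0.046	0.2245	0.85	1.008
WAT	H2	H	0.417	0.046	0.2245	0.85	1.008
TIP3	O	O	-0.834	0.21	1.7	1.5	15.999
TIP3	H1	H	0.417	0.046	0.2245	0.85	1.008
TIP3	H2	H	0.417	0.046	0.2245	0.85	1.008
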