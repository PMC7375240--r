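residue_name	atom_name	charge_e	sigma_A	epsilon_kcal
ALA	N	-0.400	3.25	0.170
ALA	CA	0.350	3.55	0.070
ALA	C	0.550	3.55	0.070
ALA	O	-0.500	2.96	0.210
ALA	CB	0.000	3.55	0.070
ARG	N	-0.400	3.25	0.170
ARG	CA	0.350	3.55	0.070
ARG	C	0.550	3.55	0.070
ARG	O	-0.500	2.96	0.210
ARG	CB	0.000	3.55	0.070
ARG	CG	0.000	3.55	0.070
ARG	CD	0.000	3.55	0.070
ARG	NE	-0.110	3.25	0.170
ARG	CZ	0.810	3.55	0.070
ARG	NH1	0.150	3.25	0.170
ARG	NH2	0.150	3.25	0.170
ASN	N	-0.400	3.25	0.170
ASN	CA	0.350	3.55	0.070
ASN	C	0.550	3.55	0.070
ASN	O	-0.500	2.96	0.210
ASN	CB	0.000	3.55	0.070
ASN	CG	0.500	3.55	0.070
ASN	OD1	-0.500	2.96	0.210
ASN	ND2	0.000	3.25	0.170
ASP	N	-0.400	3.25	0.170
ASP	CA	0.350	3.55	0.070
ASP	C	0.550	3.55	0.070
ASP	O	-0.500	2.96	0.210
ASP	CB	0.000	3.55	0.070
ASP	CG	0.360	3.55	0.070
ASP	OD1	-0.680	2.96	0.210
ASP	OD2	-0.680	2.96	0.210
CYS	N	-0.400	3.25	0.170
CYS	CA	0.350	3.55	0.070
CYS	C	0.550	3.55	0.070
CYS	O	-0.500	2.96	0.210
CYS	CB	0.180	3.55	0.070
CYS	SG	-0.180	3.55	0.250
GLN	N	-0.400	3.25	0.170
GLN	CA	0.350	3.55	0.070
GLN	C	0.550	3.55	0.070
GLN	O	-0.500	2.96	0.210
GLN	CB	0.000	3.55	0.070
GLN	CG	0.000	3.55	0.070
GLN	CD	0.500	3.55	0.070
GLN	OE1	-0.500	2.96	0.210
GLN	NE2	0.000	3.25	0.170
GLU	N	-0.400	3.25	0.170
GLU	CA	0.350	3.55	0.070
GLU	C	0.550	3.55	0.070
GLU	O	-0.500	2.96	0.210
GLU	CB	0.000	3.55	0.070
GLU	CG	0.000	3.55	0.070
GLU	CD	0.360	3.55	0.070
GLU	OE1	-0.680	2.96	0.210
GLU	OE2	-0.680	2.96	0.210
GLY	N	-0.400	3.25	0.170
GLY	CA	0.350	3.55	0.070
GLY	C	0.550	3.55	0.070
GLY	O	-0.500	2.96	0.210
HIS	N	-0.400	3.25	0.170
HIS	CA	0.350	3.55	0.070
HIS	C	0.550	3.55	0.070
HIS	O	-0.500	2.96	0.210
HIS	CB	0.000	3.55	0.070
HIS	CG	0.100	3.55	0.070
HIS	ND1	-0.290	3.25	0.170
HIS	CD2	0.060	3.55	0.070
HIS	CE1	0.180	3.55	0.070
HIS	NE2	-0.050	3.25	0.170
ILE	N	-0.400	3.25	0.170
ILE	CA	0.350	3.55	0.070
ILE	C	0.550	3.55	0.070
ILE	O	-0.500	2.96	0.210
ILE	CB	0.000	3.55	0.070
ILE	CG1	0.000	3.55	0.070
ILE	CG2	0.000	3.55	0.070
ILE	CD1	0.000	3.55	0.070
LEU	N	-0.400	3.25	0.170
LEU	CA	0.350	3.55	0.070
LEU	C	0.550	3.55	0.070
LEU	O	-0.500	2.96	0.210
LEU	CB	0.000	3.55	0.070
LEU	CG	0.000	3.55	0.070
LEU	CD1	0.000	3.55	0.070
LEU	CD2	0.000	3.55	0.070
LYS	N	-0.400	3.25	0.170
LYS	CA	0.350	3.55	0.070
LYS	C	0.550	3.55	0.070
LYS	O	-0.500	2.96	0.210
LYS	CB	0.000	3.55	0.070
LYS	CG	0.000	3.55	0.070
LYS	CD	0.000	3.55	0.070
LYS	CE	0.310	3.55	0.070
LYS	NZ	0.690	3.25	0.170
MET	N	-0.400	3.25	0.170
MET	CA	0.350	3.55	0.070
MET	C	0.550	3.55	0.070
MET	O	-0.500	2.96	0.210
MET	CB	0.000	3.55	0.070
MET	CG	0.120	3.55	0.070
MET	SD	-0.240	3.55	0.250
MET	CE	0.120	3.55	0.070
PHE	N	-0.400	3.25	0.170
PHE	CA	0.350	3.55	0.070
PHE	C	0.550	3.55	0.070
PHE	O	-0.500	2.96	0.210
PHE	CB	0.000	3.55	0.070
PHE	CG	0.000	3.55	0.070
PHE	CD1	0.000	3.55	0.070
PHE	CD2	0.000	3.55	0.070
PHE	CE1	0.000	3.55	0.070
PHE	CE2	0.000	3.55	0.070
PHE	CZ	0.000	3.55	0.070
PRO	N	-0.400	3.25	0.170
PRO	CA	0.350	3.55	0.070
PRO	C	0.550	3.55	0.070
PRO	O	-0.500	2.96	0.210
PRO	CB	0.000	3.55	0.070
PRO	CG	0.000	3.55	0.070
PRO	CD	0.000	3.55	0.070
SER	N	-0.400	3.25	0.170
SER	CA	0.350	3.55	0.070
SER	C	0.550	3.55	0.070
SER	O	-0.500	2.96	0.210
SER	CB	0.250	3.55	0.070
SER	OG	-0.250	2.96	0.210
THR	N	-0.400	3.25	0.170
THR	CA	0.350	3.55	0.070
THR	C	0.550	3.55	0.070
THR	O	-0.500	2.96	0.210
THR	CB	0.250	3.55	0.070
THR	OG1	-0.250	2.96	0.210
THR	CG2	0.000	3.55	0.070
TRP	N	-0.400	3.25	0.170
TRP	CA	0.350	3.55	0.070
TRP	C	0.550	3.55	0.070
TRP	O	-0.500	2.96	0.210
TRP	CB	0.000	3.55	0.070
TRP	CG	0.000	3.55	0.070
TRP	CD1	0.060	3.55	0.070
TRP	CD2	0.000	3.55	0.070
TRP	NE1	-0.120	3.25	0.170
TRP	CE2	0.060	3.55	0.070
TRP	CE3	0.000	3.55	0.070
TRP	CZ2	0.000	3.55	0.070
TRP	CZ3	0.000	3.55	0.070
TRP	CH2	0.000	3.55	0.070
TYR	N	-0.400	3.25	0.170
TYR	CA	0.350	3.55	0.070
TYR	C	0.550	3.55	0.070
TYR	O	-0.500	2.96	0.210
TYR	CB	0.000	3.55	0.070
TYR	CG	0.000	3.55	0.070
TYR	CD1	0.000	3.55	0.070
TYR	CD2	0.000	3.55	0.070
TYR	CE1	0.000	3.55	0.070
TYR	CE2	0.000	3.55	0.070
TYR	CZ	0.150	3.55	0.070
TYR	OH	-0.150	2.96	0.210
VAL	N	-0.400	3.25	0.170
VAL	CA	0.350	3.55	0.070
VAL	C	0.550	3.55	0.070
VAL	O	-0.500	2.96	0.210
VAL	CB	0.000	3.55	0.070
VAL	CG1	0.000	3.55	0.070
VAL	CG2	0.000	3.55	0.070
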