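resid	atom	ref1	ref2	ref3	bond	angle	tortype	offset
ALA	CB	C	N	CA	1.530	110.5	fixed	122.5
SER	CB	C	N	CA	1.530	110.5	fixed	122.5
SER	OG	N	CA	CB	1.417	110.8	chi1	0
CYS	CB	C	N	CA	1.530	110.5	fixed	122.5
CYS	SG	N	CA	CB	1.808	114.4	chi1	0
THR	CB	C	N	CA	1.540	110.5	fixed	122.5
THR	OG1	N	CA	CB	1.433	109.6	chi1	0
THR	CG2	N	CA	CB	1.521	110.5	chi1	-120
VAL	CB	C	N	CA	1.540	110.5	fixed	122.5
VAL	CG1	N	CA	CB	1.521	110.4	chi1	0
VAL	CG2	N	CA	CB	1.521	110.4	chi1	120
ILE	CB	C	N	CA	1.540	110.5	fixed	122.5
ILE	CG1	N	CA	CB	1.530	110.4	chi1	0
ILE	CG2	N	CA	CB	1.521	110.5	chi1	-120
ILE	CD1	CA	CB	CG1	1.513	113.8	chi2	0
LEU	CB	C	N	CA	1.530	110.5	fixed	122.5
LEU	CG	N	CA	CB	1.530	116.3	chi1	0
LEU	CD1	CA	CB	CG	1.521	110.5	chi2	0
LEU	CD2	CA	CB	CG	1.521	110.5	chi2	120
PRO	CB	C	N	CA	1.530	103.0	fixed	115.0
PRO	CG	N	CA	CB	1.495	104.5	chi1	0
PRO	CD	CA	CB	CG	1.507	106.1	chi2	0
MET	CB	C	N	CA	1.530	110.5	fixed	122.5
MET	CG	N	CA	CB	1.520	114.1	chi1	0
MET	SD	CA	CB	CG	1.803	112.7	chi2	0
MET	CE	CB	CG	SD	1.791	100.9	chi3	0
PHE	CB	C	N	CA	1.530	110.5	fixed	122.5
PHE	CG	N	CA	CB	1.502	113.8	chi1	0
PHE	CD1	CA	CB	CG	1.384	120.8	chi2	0
PHE	CD2	CA	CB	CG	1.384	120.8	chi2	180
PHE	CE1	CB	CG	CD1	1.382	120.8	fixed	180
PHE	CE2	CB	CG	CD2	1.382	120.8	fixed	180
PHE	CZ	CG	CD1	CE1	1.382	120.1	fixed	0
TYR	CB	C	N	CA	1.530	110.5	fixed	122.5
TYR	CG	N	CA	CB	1.512	113.9	chi1	0
TYR	CD1	CA	CB	CG	1.389	120.8	chi2	0
TYR	CD2	CA	CB	CG	1.389	120.8	chi2	180
TYR	CE1	CB	CG	CD1	1.382	121.2	fixed	180
TYR	CE2	CB	CG	CD2	1.382	121.2	fixed	180
TYR	CZ	CG	CD1	CE1	1.378	119.6	fixed	0
TYR	OH	CD1	CE1	CZ	1.376	119.9	fixed	180
TRP	CB	C	N	CA	1.530	110.5	fixed	122.5
TRP	CG	N	CA	CB	1.498	113.6	chi1	0
TRP	CD1	CA	CB	CG	1.365	126.9	chi2	0
TRP	CD2	CA	CB	CG	1.433	126.7	chi2	180
TRP	NE1	CB	CG	CD1	1.374	110.2	fixed	180
TRP	CE2	CG	CD1	NE1	1.370	109.0	fixed	0
TRP	CE3	CD1	CG	CD2	1.398	133.9	fixed	180
TRP	CZ2	CG	CD2	CE2	1.394	122.4	fixed	180
TRP	CZ3	CG	CD2	CE3	1.400	118.8	fixed	180
TRP	CH2	CD2	CE2	CZ2	1.368	117.5	fixed	0
HIS	CB	C	N	CA	1.530	110.5	fixed	122.5
HIS	CG	N	CA	CB	1.492	113.7	chi1	0
HIS	ND1	CA	CB	CG	1.380	122.7	chi2	0
HIS	CD2	CA	CB	CG	1.354	131.0	chi2	180
HIS	CE1	CB	CG	ND1	1.326	109.2	fixed	180
HIS	NE2	CB	CG	CD2	1.373	107.2	fixed	180
ASP	CB	C	N	CA	1.530	110.5	fixed	122.5
ASP	CG	N	CA	CB	1.516	112.6	chi1	0
ASP	OD1	CA	CB	CG	1.249	118.4	chi2	0
ASP	OD2	CA	CB	CG	1.249	118.4	chi2	180
ASN	CB	C	N	CA	1.530	110.5	fixed	122.5
ASN	CG	N	CA	CB	1.516	112.6	chi1	0
ASN	OD1	CA	CB	CG	1.231	120.8	chi2	0
ASN	ND2	CA	CB	CG	1.328	116.4	chi2	180
GLU	CB	C	N	CA	1.530	110.5	fixed	122.5
GLU	CG	N	CA	CB	1.520	114.1	chi1	0
GLU	CD	CA	CB	CG	1.516	112.6	chi2	0
GLU	OE1	CB	CG	CD	1.249	118.4	chi3	0
GLU	OE2	CB	CG	CD	1.249	118.4	chi3	180
GLN	CB	C	N	CA	1.530	110.5	fixed	122.5
GLN	CG	N	CA	CB	1.520	114.1	chi1	0
GLN	CD	CA	CB	CG	1.516	112.6	chi2	0
GLN	OE1	CB	CG	CD	1.231	120.8	chi3	0
GLN	NE2	CB	CG	CD	1.328	116.4	chi3	180
LYS	CB	C	N	CA	1.530	110.5	fixed	122.5
LYS	CG	N	CA	CB	1.520	114.1	chi1	0
LYS	CD	CA	CB	CG	1.520	111.3	chi2	0
LYS	CE	CB	CG	CD	1.520	111.3	chi3	0
LYS	NZ	CG	CD	CE	1.489	111.9	chi4	0
ARG	CB	C	N	CA	1.530	110.5	fixed	122.5
ARG	CG	N	CA	CB	1.520	114.1	chi1	0
ARG	CD	CA	CB	CG	1.520	111.3	chi2	0
ARG	NE	CB	CG	CD	1.461	111.8	chi3	0
ARG	CZ	CG	CD	NE	1.329	124.4	chi4	0
ARG	NH1	CD	NE	CZ	1.326	120.0	fixed	0
ARG	NH2	CD	NE	CZ	1.326	120.0	fixed	180
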