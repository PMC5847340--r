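# Planar group definitions: member atom names and the three-atom plane triple.
# kind: sp2 sidechain groups, the backbone peptide unit, the C-terminal
# carboxyl, and sp3 control planes. Peptide-unit atom names carry an _i or
# _ip1 suffix marking which flanking residue (i or i+1) the atom belongs to.
# Edit and pass to sp2Definitions() to test alternative atom tables.
identity	kind	aromatic	members	triple
F	sidechain	TRUE	CG,CD1,CD2,CE1,CE2,CZ	CG,CD1,CD2
Y	sidechain	TRUE	CG,CD1,CD2,CE1,CE2,CZ	CG,CD1,CD2
W	sidechain	TRUE	CG,CD1,CD2,NE1,CE2,CE3,CZ2,CZ3,CH2	CD2,CE2,CE3
H	sidechain	TRUE	CG,ND1,CD2,CE1,NE2	CG,ND1,CD2
R	sidechain	FALSE	NE,CZ,NH1,NH2	NE,CZ,NH1
Q	sidechain	FALSE	CD,OE1,NE2	OE1,CD,NE2
N	sidechain	FALSE	CG,OD1,ND2	OD1,CG,ND2
E	sidechain	FALSE	CD,OE1,OE2	OE1,CD,OE2
D	sidechain	FALSE	CG,OD1,OD2	OD1,CG,OD2
PEPTIDE	backbone	FALSE	CA_i,C_i,O_i,N_ip1,CA_ip1	O_i,C_i,N_ip1
CTERM	cterm	FALSE	C,O,OXT	O,C,OXT
L	sp3	FALSE	CD1,CG,CD2	CD1,CG,CD2
V	sp3	FALSE	CG1,CB,CG2	CG1,CB,CG2
M	sp3	FALSE	CE,SD,CG	CE,SD,CG
I	sp3	FALSE	CD1,CG1,CB	CD1,CG1,CB
C	sp3	FALSE	SG,CB,CA	SG,CB,CA
S	sp3	FALSE	OG,CB,CA	OG,CB,CA
T	sp3	FALSE	OG1,CB,CG2	OG1,CB,CG2
K	sp3	FALSE	NZ,CE,CD	NZ,CE,CD
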