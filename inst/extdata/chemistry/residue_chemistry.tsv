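residue	polymer	record	atom	value
A	rna	acceptor	OP1	2
A	rna	acceptor	OP2	2
A	rna	acceptor	O5'	2
A	rna	acceptor	O4'	2
A	rna	acceptor	O3'	2
A	rna	acceptor	O2'	2
A	rna	donor	O2'	1
A	rna	acceptor	N1	1
A	rna	acceptor	N3	1
A	rna	acceptor	N7	1
A	rna	donor	N6	2
A	rna	amine	N6	C6|N1|C5
C	rna	acceptor	OP1	2
C	rna	acceptor	OP2	2
C	rna	acceptor	O5'	2
C	rna	acceptor	O4'	2
C	rna	acceptor	O3'	2
C	rna	acceptor	O2'	2
C	rna	donor	O2'	1
C	rna	acceptor	O2	2
C	rna	acceptor	N3	1
C	rna	donor	N4	2
C	rna	amine	N4	C4|N3|C5
G	rna	acceptor	OP1	2
G	rna	acceptor	OP2	2
G	rna	acceptor	O5'	2
G	rna	acceptor	O4'	2
G	rna	acceptor	O3'	2
G	rna	acceptor	O2'	2
G	rna	donor	O2'	1
G	rna	acceptor	O6	2
G	rna	acceptor	N3	1
G	rna	acceptor	N7	1
G	rna	donor	N1	1
G	rna	donor	N2	2
G	rna	amine	N2	C2|N1|N3
U	rna	acceptor	OP1	2
U	rna	acceptor	OP2	2
U	rna	acceptor	O5'	2
U	rna	acceptor	O4'	2
U	rna	acceptor	O3'	2
U	rna	acceptor	O2'	2
U	rna	donor	O2'	1
U	rna	acceptor	O2	2
U	rna	acceptor	O4	2
U	rna	donor	N3	1
DA	dna	acceptor	OP1	2
DA	dna	acceptor	OP2	2
DA	dna	acceptor	O5'	2
DA	dna	acceptor	O4'	2
DA	dna	acceptor	O3'	2
DA	dna	acceptor	N1	1
DA	dna	acceptor	N3	1
DA	dna	acceptor	N7	1
DC	dna	acceptor	OP1	2
DC	dna	acceptor	OP2	2
DC	dna	acceptor	O5'	2
DC	dna	acceptor	O4'	2
DC	dna	acceptor	O3'	2
DC	dna	acceptor	O2	2
DC	dna	acceptor	N3	1
DG	dna	acceptor	OP1	2
DG	dna	acceptor	OP2	2
DG	dna	acceptor	O5'	2
DG	dna	acceptor	O4'	2
DG	dna	acceptor	O3'	2
DG	dna	acceptor	O6	2
DG	dna	acceptor	N3	1
DG	dna	acceptor	N7	1
DT	dna	acceptor	OP1	2
DT	dna	acceptor	OP2	2
DT	dna	acceptor	O5'	2
DT	dna	acceptor	O4'	2
DT	dna	acceptor	O3'	2
DT	dna	acceptor	O2	2
DT	dna	acceptor	O4	2
ALA	protein	acceptor	O	2
ALA	protein	donor	N	1
ARG	protein	acceptor	O	2
ARG	protein	donor	N	1
ASN	protein	acceptor	O	2
ASN	protein	donor	N	1
ASP	protein	acceptor	O	2
ASP	protein	donor	N	1
CYS	protein	acceptor	O	2
CYS	protein	donor	N	1
GLN	protein	acceptor	O	2
GLN	protein	donor	N	1
GLU	protein	acceptor	O	2
GLU	protein	donor	N	1
GLY	protein	acceptor	O	2
GLY	protein	donor	N	1
HIS	protein	acceptor	O	2
HIS	protein	donor	N	1
ILE	protein	acceptor	O	2
ILE	protein	donor	N	1
LEU	protein	acceptor	O	2
LEU	protein	donor	N	1
LYS	protein	acceptor	O	2
LYS	protein	donor	N	1
MET	protein	acceptor	O	2
MET	protein	donor	N	1
PHE	protein	acceptor	O	2
PHE	protein	donor	N	1
PRO	protein	acceptor	O	2
SER	protein	acceptor	O	2
SER	protein	donor	N	1
THR	protein	acceptor	O	2
THR	protein	donor	N	1
TRP	protein	acceptor	O	2
TRP	protein	donor	N	1
TYR	protein	acceptor	O	2
TYR	protein	donor	N	1
VAL	protein	acceptor	O	2
VAL	protein	donor	N	1
ASP	protein	sidechain_acceptor	OD1	2
ASP	protein	sidechain_acceptor	OD2	2
GLU	protein	sidechain_acceptor	OE1	2
GLU	protein	sidechain_acceptor	OE2	2
ASN	protein	sidechain_acceptor	OD1	2
ASN	protein	sidechain_donor	ND2	2
GLN	protein	sidechain_acceptor	OE1	2
GLN	protein	sidechain_donor	NE2	2
SER	protein	sidechain_acceptor	OG	2
SER	protein	sidechain_donor	OG	1
THR	protein	sidechain_acceptor	OG1	2
THR	protein	sidechain_donor	OG1	1
TYR	protein	sidechain_acceptor	OH	2
TYR	protein	sidechain_donor	OH	1
HIS	protein	sidechain_acceptor	ND1	1
HIS	protein	sidechain_acceptor	NE2	1
LYS	protein	sidechain_donor	NZ	3
ARG	protein	sidechain_donor	NE	1
ARG	protein	sidechain_donor	NH1	2
ARG	protein	sidechain_donor	NH2	2
TRP	protein	sidechain_donor	NE1	1
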