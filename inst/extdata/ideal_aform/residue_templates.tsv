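residue	atom	x	y	z
A	O4'	-2.0733	6.6962	-0.303
A	C1'	-2.4775	5.3755	0
A	C2'	-3.1637	5.4365	1.3639
A	C3'	-2.5418	6.6944	1.9611
A	C4'	-2.4137	7.6111	0.7517
A	O2'	-4.5642	5.5453	1.2114
A	C5'	-1.3459	8.6714	0.851
A	O3'	-3.3198	7.314	2.9788
A	O5'	-0.06	8.0986	1.1544
A	P	1.252	9.0017	1.1814
A	OP1	2.3936	8.1424	1.5858
A	OP2	0.9483	10.231	1.9572
A	N9	-1.291	4.498	0
A	C8	0.024	4.897	0
A	N7	0.877	3.902	0
A	C5	0.071	2.771	0
A	C6	0.369	1.398	0
A	N6	1.611	0.909	0
A	N1	-0.668	0.532	0
A	C2	-2.077	1.018	0
A	N3	-2.417	2.344	0
A	C4	-1.267	3.124	0
G	O4'	-2.0733	6.6962	-0.303
G	C1'	-2.4775	5.3755	0
G	C2'	-3.1637	5.4365	1.3639
G	C3'	-2.5418	6.6944	1.9611
G	C4'	-2.4137	7.6111	0.7517
G	O2'	-4.5642	5.5453	1.2114
G	C5'	-1.3459	8.6714	0.851
G	O3'	-3.3198	7.314	2.9788
G	O5'	-0.06	8.0986	1.1544
G	P	1.252	9.0017	1.1814
G	OP1	2.3936	8.1424	1.5858
G	OP2	0.9483	10.231	1.9572
G	N9	-1.289	4.551	0
G	C8	0.023	4.962	0
G	N7	0.87	3.969	0
G	C5	0.071	2.833	0
G	C6	0.424	1.46	0
G	O6	1.554	0.955	0
G	N1	-0.7	0.641	0
G	C2	-2.059	1.087	0
G	N2	-2.949	0.139	0
G	N3	-2.427	2.392	0
G	C4	-1.265	3.177	0
C	O4'	-2.0733	6.6962	-0.303
C	C1'	-2.4775	5.3755	0
C	C2'	-3.1637	5.4365	1.3639
C	C3'	-2.5418	6.6944	1.9611
C	C4'	-2.4137	7.6111	0.7517
C	O2'	-4.5642	5.5453	1.2114
C	C5'	-1.3459	8.6714	0.851
C	O3'	-3.3198	7.314	2.9788
C	O5'	-0.06	8.0986	1.1544
C	P	1.252	9.0017	1.1814
C	OP1	2.3936	8.1424	1.5858
C	OP2	0.9483	10.231	1.9572
C	N1	-1.285	4.542	0
C	C2	-1.472	3.158	0
C	O2	-2.628	2.709	0
C	N3	-0.391	2.344	0
C	C4	0.837	2.868	0
C	N4	1.875	2.027	0
C	C5	1.056	4.275	0
C	C6	-0.023	5.068	0
U	O4'	-2.0733	6.6962	-0.303
U	C1'	-2.4775	5.3755	0
U	C2'	-3.1637	5.4365	1.3639
U	C3'	-2.5418	6.6944	1.9611
U	C4'	-2.4137	7.6111	0.7517
U	O2'	-4.5642	5.5453	1.2114
U	C5'	-1.3459	8.6714	0.851
U	O3'	-3.3198	7.314	2.9788
U	O5'	-0.06	8.0986	1.1544
U	P	1.252	9.0017	1.1814
U	OP1	2.3936	8.1424	1.5858
U	OP2	0.9483	10.231	1.9572
U	N1	-1.284	4.5	0
U	C2	-1.462	3.131	0
U	O2	-2.563	2.608	0
U	N3	-0.302	2.397	0
U	C4	0.989	2.884	0
U	O4	1.935	2.094	0
U	C5	1.089	4.311	0
U	C6	-0.024	5.053	0
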