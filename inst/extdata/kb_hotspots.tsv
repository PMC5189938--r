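gene	label	aa_start	aa_end	lavage_count	recurrence_endometrial	recurrence_pancancer	novel	example_change
PIK3CA	H1047R	1047	1047	8	20	20	FALSE	H1047R
PIK3CA	E545K/A	545	545	4	14	14	FALSE	E545K
PIK3CA	E542K/A	542	542	4	13	13	FALSE	E542K
PIK3CA	R88Q	88	88	2	11	11	FALSE	R88Q
PIK3CA	Q546K	546	546	1	11	11	FALSE	Q546K
PIK3CA	R93W/Q	93	93	3	6	6	FALSE	R93W
PIK3CA	M1043V	1043	1043	1	6	6	FALSE	M1043V
PIK3CA	C420R	420	420	1	4	4	FALSE	C420R
PIK3CA	G106V	106	106	2	1	1	FALSE	G106V
PIK3CA	V344G	344	344	2	3	3	FALSE	V344G
PIK3CA	N345I/T	345	345	2	5	5	FALSE	N345I
PIK3CA	K111R	111	111	1	4	4	FALSE	K111R
PIK3CA	E453K	453	453	1	1	1	FALSE	E453K
PIK3CA	E81K	81	81	1	1	1	FALSE	E81K
KRAS	G12D,V	12	12	21	36	36	FALSE	G12D
KRAS	G13C	13	13	1	9	9	FALSE	G13C
KRAS	Q61L	61	61	1	3	3	FALSE	Q61L
PTEN	R130G/Q/*	130	130	7	57	57	FALSE	R130G
PTEN	Y16*	16	16	1	3	3	FALSE	Y16*
PTEN	A72fs	72	72	1	1	1	FALSE	A72fs
PTEN	G132D	132	132	1	1	1	FALSE	G132D
PTEN	I33S	33	33	1	1	1	FALSE	I33S
PTEN	I67R	67	67	1	1	1	FALSE	I67R
PTEN	D92E	92	92	1	2	2	FALSE	D92E
PTEN	G165E	165	165	1	3	3	FALSE	G165E
PTEN	R173C	173	173	1	2	2	FALSE	R173C
PTEN	I32del	32	32	1	0	0	TRUE	I32del
PTEN	W111*	111	111	1	0	0	TRUE	W111*
PTEN	Y176del	176	176	1	0	0	TRUE	Y176del
PTEN	L318fs	318	318	1	0	0	TRUE	L318fs
PTEN	T321fs	321	321	1	0	0	TRUE	T321fs
PTEN	F337fs	337	337	1	0	0	TRUE	F337fs
PTEN	K342fs	342	342	1	0	0	TRUE	K342fs
PTEN	P95L	95	95	1	0	0	TRUE	P95L
PTEN	K128Q	128	128	1	0	0	TRUE	K128Q
PTEN	C211Y	211	211	1	0	0	TRUE	C211Y
PIK3R1	D578H/A	578	578	2	5	5	FALSE	D578H
PIK3R1	T576delT	576	576	1	2	2	FALSE	T576delT
PIK3R1	Y580fs	580	580	1	1	1	FALSE	Y580fs
PIK3R1	Y580D	580	580	1	3	3	FALSE	Y580D
PIK3R1	R514C	514	514	1	1	1	FALSE	R514C
PIK3R1	R461*	461	461	1	2	2	FALSE	R461*
PIK3R1	Y463_L466del	463	466	1	0	0	TRUE	Y463_L466del
PIK3R1	E558fs	558	558	1	0	0	TRUE	E558fs
PIK3R1	L570fs	570	570	1	0	0	TRUE	L570fs
PIK3R1	D464del	464	464	1	0	0	TRUE	D464del
ARID1A	R1989*	1989	1989	1	9	9	FALSE	R1989*
ARID1A	R1722*	1722	1722	2	2	2	FALSE	R1722*
ARID1A	R1446*	1446	1446	1	1	1	FALSE	R1446*
ARID1A	E1444*	1444	1444	1	0	0	TRUE	E1444*
FGFR2	S252W	252	252	4	9	9	FALSE	S252W
FBXW7	R505C/G	505	505	3	6	6	FALSE	R505C
FBXW7	R479Q	479	479	3	1	1	FALSE	R479Q
FBXW7	R465C	465	465	1	7	7	FALSE	R465C
FBXW7	R441L	441	441	1	1	1	FALSE	R441L
TP53	R273H	273	273	1	9	9	FALSE	R273H
TP53	S241F	241	241	1	3	3	FALSE	S241F
TP53	S166fs	166	166	1	0	0	TRUE	S166fs
TP53	Q165fs	165	165	1	0	0	TRUE	Q165fs
CTNNB1	S37F	37	37	1	20	20	FALSE	S37F
CTNNB1	D32Y/A	32	32	2	12	12	FALSE	D32Y
CTNNB1	S45F	45	45	2	3	3	FALSE	S45F
CTNNB1	T41A	41	41	1	5	5	FALSE	T41A
RB1	R445*	445	445	1	0	0	TRUE	R445*
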