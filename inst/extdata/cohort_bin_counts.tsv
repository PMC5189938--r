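gene	fraction	bin1	bin2	bin3
PTEN	cell_pellet	17	1	4
KRAS	cell_pellet	16	1	2
PIK3CA	cell_pellet	28	6	2
TP53	cell_pellet	7	2	0
PIK3R1	cell_pellet	7	1	0
FGFR2	cell_pellet	3	2	0
FBXW7	cell_pellet	5	1	1
CTNNB1	cell_pellet	1	1	1
ATM	cell_pellet	1	1	0
APC	cell_pellet	1	0	0
ARID1A	cell_pellet	3	0	1
RB1	cell_pellet	1	0	1
PTEN	cfdna	20	0	4
KRAS	cfdna	10	1	1
PIK3CA	cfdna	31	1	2
TP53	cfdna	4	1	2
PIK3R1	cfdna	10	0	0
FGFR2	cfdna	3	0	0
FBXW7	cfdna	4	0	0
CTNNB1	cfdna	4	2	0
ATM	cfdna	4	1	0
APC	cfdna	2	0	0
ARID1A	cfdna	2	0	2
RB1	cfdna	0	0	2
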