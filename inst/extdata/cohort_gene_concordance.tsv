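gene	mut_both	unique_patients	cancer_patients
PTEN	8	5	3
KRAS	7	6	0
PIK3CA	14	10	2
TP53	3	2	2
PIK3R1	3	2	0
FGFR2	2	2	1
FBXW7	1	1	0
CTNNB1	2	2	1
ATM	1	1	1
APC	1	1	1
ARID1A	3	1	1
RB1	2	1	1
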