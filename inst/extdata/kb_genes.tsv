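symbol	role	major_ec_driver	on_12_gene_panel	tcga_hotspot_count	tcga_mutation_count
PIK3CA	oncogene	TRUE	TRUE	86	137
KRAS	oncogene	TRUE	TRUE	45	49
PTEN	tumor_suppressor	TRUE	TRUE	62	163
PIK3R1	tumor_suppressor	TRUE	TRUE	3	81
ARID1A	tumor_suppressor	TRUE	TRUE	12	82
FGFR2	oncogene	TRUE	TRUE	9	38
FBXW7	tumor_suppressor	TRUE	TRUE	6	38
TP53	tumor_suppressor	TRUE	TRUE	0	68
CTNNB1	oncogene	TRUE	TRUE	20	73
RB1	tumor_suppressor	TRUE	TRUE	0	25
ATM	tumor_suppressor	TRUE	TRUE	0	0
APC	tumor_suppressor	TRUE	TRUE	0	0
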