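chrom	pos	ref	alt	maf
chr1	51000619	C	T	0.4
chr2	52000352	C	T	0.318
chr3	53000364	T	A	0.348
chr4	54000015	T	G	0.439
chr5	55000723	A	G	0.473
chr6	56000125	T	G	0.433
chr7	57000941	G	A	0.338
chr8	58000422	G	A	0.49
chr9	59000199	C	T	0.442
chr10	60000448	C	G	0.35
chr11	61000972	C	G	0.451
chr12	62000887	C	T	0.378
chr13	63000847	C	G	0.303
chr14	64000100	C	G	0.308
chr15	65000155	C	G	0.416
chr16	66000967	T	A	0.49
chr17	67000692	G	C	0.437
chr18	68000703	G	C	0.338
chr19	69000756	A	C	0.346
chr20	70000668	G	C	0.412
chr21	71000724	T	A	0.374
chr22	72000054	A	G	0.465
chr1	73000511	C	G	0.406
chr2	74000776	A	G	0.306
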