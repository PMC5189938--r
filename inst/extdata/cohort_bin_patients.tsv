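fraction	bin	cancer	total
cell_pellet	1	4	43
cell_pellet	2	3	11
cell_pellet	3	2	4
cfdna	1	5	33
cfdna	2	1	4
cfdna	3	3	4
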