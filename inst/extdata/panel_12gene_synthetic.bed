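chr10	89623195	89623333	PTEN
chr10	89623333	89623471	PTEN
chr10	89623471	89623609	PTEN
chr10	89623609	89623747	PTEN
chr10	89623747	89623885	PTEN
chr10	89623885	89624023	PTEN
chr10	89624023	89624161	PTEN
chr10	89624161	89624299	PTEN
chr10	89624299	89624437	PTEN
chr10	89624437	89624575	PTEN
chr10	89624575	89624713	PTEN
chr10	89624713	89624851	PTEN
chr3	178866311	178866449	PIK3CA
chr3	178866449	178866587	PIK3CA
chr3	178866587	178866725	PIK3CA
chr3	178866725	178866863	PIK3CA
chr3	178866863	178867001	PIK3CA
chr3	178867001	178867139	PIK3CA
chr3	178867139	178867277	PIK3CA
chr3	178867277	178867415	PIK3CA
chr3	178867415	178867553	PIK3CA
chr3	178867553	178867691	PIK3CA
chr3	178867691	178867829	PIK3CA
chr3	178867829	178867967	PIK3CA
chr3	178867967	178868105	PIK3CA
chr3	178868105	178868243	PIK3CA
chr17	7571720	7571858	TP53
chr17	7571858	7571996	TP53
chr17	7571996	7572134	TP53
chr17	7572134	7572272	TP53
chr17	7572272	7572410	TP53
chr17	7572410	7572548	TP53
chr17	7572548	7572686	TP53
chr17	7572686	7572824	TP53
chr17	7572824	7572962	TP53
chr17	7572962	7573100	TP53
chr17	7573100	7573238	TP53
chr17	7573238	7573376	TP53
chr3	41236328	41236466	CTNNB1
chr3	41236466	41236604	CTNNB1
chr3	41236604	41236742	CTNNB1
chr3	41236742	41236880	CTNNB1
chr3	41236880	41237018	CTNNB1
chr3	41237018	41237156	CTNNB1
chr12	25358180	25358318	KRAS
chr12	25358318	25358456	KRAS
chr12	25358456	25358594	KRAS
chr12	25358594	25358732	KRAS
chr10	123237848	123237986	FGFR2
chr10	123237986	123238124	FGFR2
chr10	123238124	123238262	FGFR2
chr10	123238262	123238400	FGFR2
chr10	123238400	123238538	FGFR2
chr10	123238538	123238676	FGFR2
chr4	153242410	153242548	FBXW7
chr4	153242548	153242686	FBXW7
chr4	153242686	153242824	FBXW7
chr4	153242824	153242962	FBXW7
chr4	153242962	153243100	FBXW7
chr4	153243100	153243238	FBXW7
chr4	153243238	153243376	FBXW7
chr4	153243376	153243514	FBXW7
chr13	48877883	48878021	RB1
chr13	48878021	48878159	RB1
chr13	48878159	48878297	RB1
chr13	48878297	48878435	RB1
chr13	48878435	48878573	RB1
chr13	48878573	48878711	RB1
chr13	48878711	48878849	RB1
chr13	48878849	48878987	RB1
chr11	108093211	108093349	ATM
chr11	108093349	108093487	ATM
chr11	108093487	108093625	ATM
chr11	108093625	108093763	ATM
chr11	108093763	108093901	ATM
chr11	108093901	108094039	ATM
chr11	108094039	108094177	ATM
chr11	108094177	108094315	ATM
chr5	112043195	112043333	APC
chr5	112043333	112043471	APC
chr5	112043471	112043609	APC
chr5	112043609	112043747	APC
chr5	112043747	112043885	APC
chr5	112043885	112044023	APC
chr5	112044023	112044161	APC
chr5	112044161	112044299	APC
chr1	27022522	27022660	ARID1A
chr1	27022660	27022798	ARID1A
chr1	27022798	27022936	ARID1A
chr1	27022936	27023074	ARID1A
chr1	27023074	27023212	ARID1A
chr1	27023212	27023350	ARID1A
chr1	27023350	27023488	ARID1A
chr1	27023488	27023626	ARID1A
chr5	67511584	67511722	PIK3R1
chr5	67511722	67511860	PIK3R1
chr5	67511860	67511998	PIK3R1
chr5	67511998	67512136	PIK3R1
chr5	67512136	67512274	PIK3R1
chr5	67512274	67512412	PIK3R1
chr5	67512412	67512550	PIK3R1
chr5	67512550	67512688	PIK3R1
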