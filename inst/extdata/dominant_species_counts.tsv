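rank	code	life_type	n_individuals	percent	n_saplings	n_poles	n_adults	habitat_association
1	PARACH	Emergent	7919	8.3	6492	1276	151	high-plateau-;gap-
2	SLOATO	Upper canopy	502	0.5	222	196	84
3	POMETO	Upper canopy	480	0.5	274	147	59	low-slope+;high-plateau-
4	SEMERE	Upper canopy	619	0.6	354	234	31	high-plateau-
5	BARRPE	Upper canopy	573	0.6	314	234	25
6	GARCCO	Lower canopy	4333	4.5	2795	1448	90	high-plateau+;low-slope-
7	KNEMFU	Lower canopy	3160	3.3	2543	578	39	gap+
8	FICULA	Lower canopy	1337	1.4	761	537	39
9	CINNBE	Lower canopy	1337	1.4	938	376	23
10	CASTEC	Lower canopy	881	0.9	291	518	72	high-plateau+;low-slope-
11	CASTHY	Lower canopy	244	0.3	32	146	66	high-plateau+;low-slope-
12	CASTIN	Lower canopy	351	0.4	166	132	53	valley+;high-plateau-
13	BACCRA	Understory	3212	3.4	1814	1365	33
14	PITTKE	Treelet	20918	21.9	16439	4453	26	low-slope-;high-plateau+
15	MEZZCR	Treelet	3300	3.5	1744	1514	42	valley+;high-plateau-
16	NEPHCH	Treelet	1098	1.1	713	343	42	high-slope+
16	PHOELA	Treelet	2409	2.5	895	1496	18	low-slope-;high-plateau+
17	SAPRTE	Treelet	2698	2.8	2332	345	21	low-slope+;high-plateau-
19	DICHGE	Treelet	1222	1.3	704	473	45	high-plateau-
20	LEEACO	Treelet	1051	1.1	974	64	13
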