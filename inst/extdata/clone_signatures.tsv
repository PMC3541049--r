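phylotype_id	taxon	group	mspi_fwd	hhai_fwd	haeiii_fwd	mspi_rev	hhai_rev	haeiii_rev
AP-FeEnrich1	Geothrix fermentans-like	Geothrix	278	359	201	92	380	125
AP-FeEnrich2	Coriobacteriaceae clone	Actinobacteria	172	284	229	128	45	69
AP-FeEnrich3	Bacteroidetes clone HN19-like	Bacteroidetes	90	94	NC	83	49	116
AP-FeEnrich4	Bacteroidetes bacterium RL-C-like	Bacteroidetes	424	86	<50	33	47	112
AP-FeEnrich5	Bacteroidetes bacterium RL-C-like	Bacteroidetes	201	86	<50	33	47	112
AP-FeEnrich6	Dysgonomonas-like	Bacteroidetes	95	100	<50	120	135	116
AP-FeEnrich7	Levilinea-like	Chloroflexi	159	536	220	76	390	125
AP-FeEnrich8	Clostridium sp.	Firmicutes	179	193	271	124	403	43
AP-FeEnrich9	Acetobacterium malicum-like	Firmicutes	216	371	NC	127	401	NC
AP-FeEnrich10	Duganella-like	Burkholderiales	492	564	200	125	51	255
AP-FeEnrich11	Desulfobacca-like	Syntrophaceae	210	95	197	73	403	125
AP-FeEnrich12	Desulfobacter-like	Desulfobacter	515	95	209	127	405	125
AP-FeEnrich13	Desulfomicrobium baculatum-like	Desulfomicrobium	161	90.5	71.2	65	46	124
AP-FeEnrich14	Desulfovibrio putealis-like	Desulfovibrio	457	95	201	127	142	123
AP-FeEnrich15	Desulfovibrio putealis-like	Desulfovibrio	507	93	201	68	143	122
AP-FeEnrich16	Desulfovibrio vulgaris-like	Desulfovibrio	289	57	75	74	270	35
AP-FeEnrich17	Geobacter pelophilus-like	Geobacter	164	93	217	126	405	124
AP-FeEnrich18	Aeromonas salmonicida-like	Aeromonas	90	215	<50	123	221	124
AP-FeEnrich19	Aeromonas jandaei-like	Aeromonas	90	215	<50	123	221	124
AP-FeEnrich20	Shewanella sp.	Shewanella	496	574	<50	127	49	123
AP-FeEnrich21	Serratia plymuthica-like	Enterobacteriaceae	493	373	206	127	49	123
AP-FeEnrich22	Serratia fonticola-like	Enterobacteriaceae	494	371	<50	127	49	123
AP-FeEnrich23	Klebsiella oxytoca-like	Enterobacteriaceae	494	371	<50	127	49	123
AP-FeEnrich24	Spirochaetes bacterium SA-8-like	Spirochaetes	210	62	210	126	146	125
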