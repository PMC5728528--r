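taxon_group	code	guild	n_specimens	n_larva	n_pupa	n_adult	n_morphospecies	n_bins	pct_family	pct_subfamily	pct_genus	pct_species
Agathidinae	B	parasitoid	1	1	0	0	1	1	100.0	100.0	100.0	0.0
Anomaloninae	I	parasitoid	1	0	0	1	1	1	100.0	100.0	100.0	100.0
Banchinae	I	parasitoid	5	0	0	5	5	4	100.0	50.0	50.0	25.0
Campopleginae	I	parasitoid	80	1	3	76	17	15	100.0	60.0	53.3	33.3
Cryptinae	I	parasitoid	4	0	0	4	3	3	100.0	66.7	66.7	66.7
Entedoninae	CH	parasitoid	2	0	0	2	1	1	100.0	0.0	0.0	0.0
Eulophinae	CH	parasitoid	104	1	3	100	6	14	92.9	64.3	64.3	14.3
Euphorinae	B	parasitoid	3	0	3	0	1	1	100.0	100.0	100.0	100.0
Homolobinae	B	parasitoid	1	0	0	1	1	1	100.0	100.0	0.0	0.0
Hormiinae	B	parasitoid	1	0	0	1	1	1	100.0	100.0	0.0	0.0
Macrocentrinae	B	parasitoid	7	0	0	7	2	2	100.0	100.0	100.0	0.0
Mesochorinae	I	parasitoid	13	0	1	12	6	5	100.0	40.0	20.0	20.0
Microgastrinae	B	parasitoid	96	0	20	76	19	26	96.2	96.2	53.8	26.9
Ophioninae	I	parasitoid	8	4	3	1	3	3	66.7	66.7	66.7	66.7
Orgilinae	B	parasitoid	2	0	0	2	1	1	100.0	100.0	0.0	0.0
Perilampinae	CH	parasitoid	6	0	6	0	1	1	0.0	0.0	0.0	0.0
Pimplinae	I	parasitoid	1	0	0	1	1	1	100.0	100.0	100.0	100.0
Pteromalinae	CH	parasitoid	1	0	1	0	1	1	100.0	0.0	0.0	0.0
Rogadinae	B	parasitoid	16	0	2	14	1	2	100.0	100.0	100.0	100.0
Tryphoninae	I	parasitoid	1	1	0	0	1	1	100.0	100.0	100.0	100.0
Dexiinae	T	parasitoid	5	0	5	0	2	2	100.0	50.0	50.0	50.0
Exoristinae	T	parasitoid	86	1	78	7	10	12	100.0	91.7	91.7	91.7
Tachininae	T	parasitoid	18	0	13	5	4	3	100.0	100.0	100.0	100.0
other	NA	parasitoid	3	2	1	0	2	2	0.0	0.0	0.0	0.0
Argidae	H	host	1	1	0	0	1	1	100.0	100.0	100.0	100.0
Bucculatricidae	L	host	10	8	0	2	3	3	100.0	100.0	100.0	66.7
Depressariidae	L	host	2	2	0	0	1	1	100.0	100.0	100.0	100.0
Drepanidae	L	host	2	2	0	0	1	1	100.0	100.0	100.0	100.0
Erebidae	L	host	26	22	1	3	6	7	100.0	100.0	100.0	100.0
Gelechiidae	L	host	6	6	0	0	6	6	100.0	100.0	83.3	83.3
Geometridae	L	host	145	99	37	9	29	34	100.0	100.0	97.1	88.2
Gracillariidae	L	host	4	4	0	0	3	3	100.0	100.0	100.0	66.7
Limacodidae	L	host	1	0	1	0	1	1	100.0	100.0	100.0	100.0
Lypusidae	L	host	20	20	0	0	3	3	100.0	100.0	100.0	66.7
Noctuidae	L	host	41	33	6	2	14	13	100.0	100.0	100.0	92.3
Nolidae	L	host	11	10	1	0	3	3	100.0	100.0	100.0	100.0
Notodontidae	L	host	8	8	0	0	5	5	100.0	100.0	100.0	100.0
Psychidae	L	host	15	11	3	1	4	6	100.0	100.0	100.0	83.3
Pyralidae	L	host	1	1	0	0	1	1	100.0	100.0	100.0	100.0
Roeslerstammiidae	L	host	2	2	0	0	2	2	100.0	100.0	100.0	100.0
Tenthredinidae	H	host	6	5	1	0	3	3	100.0	100.0	100.0	100.0
Tortricidae	L	host	26	16	4	6	8	12	100.0	100.0	100.0	100.0
Ypsolophidae	L	host	3	2	0	1	3	3	100.0	100.0	100.0	100.0
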