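chrom	pos	ref	alt	gene	consequence	splice_distance	chgvs	phgvs	dbsnp_id	gnomad_af	dbsnp_af	hgmd_described	hgmd_phenotype	mt_label	mt_score	snap2_label	snap2_score	sift_label	sift_score	pp2_label	pp2_score	phdsnp_label	phdsnp_score	bdgp_delta	netgene2_delta	assp_delta	cadd_splice
9	107549242	G	A	ABCA1	missense		c.6220G>A	p.G2074S	rs1230573600			FALSE		PP	0.999	PP	69	PP	0.00	PP	0.999	PP	7				
9	107550232	C	G	ABCA1	missense		c.6173C>G	p.A2058G				FALSE		PP	0.999	PP	31	PP	0.00	PP	0.998	PP	6				
9	107599296	T	C	ABCA1	missense		c.1276T>C	p.F426L	rs201586430			FALSE		PP	0.999	PP	50	PP	0.00	PP	0.999	PP	4				
2	44040359	T	C	ABCG5	missense		c.1852T>C	p.S618P	rs137996263			FALSE		PP	0.998	PP	51	PP	0.00	PP	0.945	PP	8				
2	44051085	C	G	ABCG5	missense		c.1291C>G	p.P431A				FALSE		PP	0.999	PP	9	NPP	0.94	PP	1	NPP	4				
19	8435981	G	A	ANGPTL4	missense		c.703G>A	p.V235M	rs866158597			FALSE		PP	0.999	PP	28	NPP	0.14	PP	0.999	PP	7				
2	21225938	C	A	APOB	missense		c.12356C>A	p.A4119D				FALSE		NPP	0.999	PP	56	PP	0.00	PP	0.989	PP	1				
2	21227295	T	C	APOB	missense		c.11933T>C	p.I3978T	rs1458765902			FALSE		PP	0.999	PP	63	PP	0.00	PP	0.977	PP	0				
2	21229970	A	G	APOB	missense		c.9770A>G	p.N3257S	rs146178619			FALSE		PP	0.984	PP	4	PP	0.00	NPP	0.073	PP	5				
2	21230600	C	T	APOB	missense		c.9140C>T	p.T3047M	rs61742323			FALSE		NPP	0.999	PP	17	PP	0.00	PP	0.625	NPP	6				
2	21233163	G	T	APOB	missense		c.6577G>T	p.D2193Y				FALSE		NPP	0.999	PP	42	PP	0.00	NPP	0.396	PP	0				
2	21238007	C	A	APOB	missense		c.3634C>A	p.L1212M	rs61736761			FALSE		NPP	0.989	PP	10	PP	0.00	PP	1	NPP	7				
2	21246505	G	A	APOB	missense		c.2496G>A	p.M832I	rs773987185			FALSE		PP	0.738	NPP	-55	PP	0.03	PP	0.592	NPP	4				
7	80276161	CA	C	CD36	frameshift		c.107del	p.K36Rfs*41	rs754478799			FALSE		PP	1	-		-		-		-					
7	80293767	G	T	CD36	missense		c.655G>T	p.D219Y	rs201715989			FALSE		PP	0.998	PP	47	PP	0.01	NPP	0.139	PP	9				
7	80299343	G	A	CD36	intronic	5	c.818+5G>A		rs748146857			FALSE		PP	1									24.24	34.04	11.06	21.3
8	59405037	C	T	CYP7A1	missense		c.1090C>T	p.R364W	rs149291486			FALSE		PP	0.999	PP	93	PP	0.00	PP	1	PP	9				
16	67976376	A	G	LCAT	missense		c.638A>G	p.Y213C	rs1186446170			FALSE		PP	0.989	PP	29	PP	0.01	PP	1	PP	6				
15	58838165	G	T	LIPC	missense		c.799G>T	p.G267C	rs540524619			FALSE		PP	0.999	PP	60	PP	0.01	PP	1	PP	8				
6	160966559	C	T	LPA	missense		c.5311C>T	p.R1771C	rs139145675			FALSE		PP	0.999	PP	20	PP	0.00	PP	1	PP	7				
6	160969591	C	T	LPA	stop_gained		c.5074C>T	p.R1692*	rs757921434			FALSE		PP	1	-		-		-		-					
6	160998167	G	A	LPA	splice_donor	1	c.4631+1G>A		rs200099994			FALSE		PP	1									>20	-	>20	31
6	161006084	C	T	LPA	missense		c.4283C>T	p.P1428L	rs76144756			FALSE		NPP	0.996	PP	33	PP	0.02	PP	1	PP	5				
8	19819628	T	G	LPL	missense		c.1325T>G	p.V442G	rs116403115			FALSE		PP	0.999	PP	22	PP	0.02	PP	1	NPP	3				
12	57549979	C	T	LRP1	missense		c.1330C>T	p.R444C	rs750499142			FALSE		PP	0.999	PP	44	PP	0.00	PP	1	PP	8				
12	57577915	C	T	LRP1	missense		c.5977C>T	p.R1993W	rs141826184			FALSE		PP	0.971	PP	58	PP	0.00	PP	1	PP	7				
12	57587039	G	A	LRP1	missense		c.7636G>A	p.G2546S	rs113379328			FALSE		PP	0.996	NPP	-19	NPP	0.58	PP	0.742	PP	3				
12	57599365	G	C	LRP1	missense		c.11495G>C	p.G3832A	rs149488896			FALSE		PP	0.997	PP	26	PP	0.04	PP	0.999	NPP	2				
12	57601936	G	A	LRP1	missense		c.11975G>A	p.R3992H	rs755903131			FALSE		PP	0.999	PP	6	NPP	0.22	PP	0.998	PP	7				
12	57606021	G	C	LRP1	missense		c.13471G>C	p.D4491H	rs142605462			FALSE		PP	0.999	PP	25	NPP	0.15	PP	1	NPP	4				
2	169997031	C	T	LRP2	missense		c.13133C>T	p.P4378L	rs746070288			FALSE		PP	0.999	PP	27	NPP	0.17	PP	1	PP	1				
2	170034493	G	A	LRP2	missense		c.10213G>A	p.G3405R	rs145432614			FALSE		PP	0.999	PP	28	NPP	0.48	PP	0.907	PP	4				
2	170037997	A	C	LRP2	missense		c.10130A>C	p.D3377A	rs1248351989			FALSE		PP	0.999	PP	38	NPP	0.25	PP	1	PP	1				
2	170058335	G	A	LRP2	missense		c.8255G>A	p.R2752Q	rs750566206			FALSE		PP	0.999	PP	14	PP	0.00	PP	0.999	PP	5				
2	170163815	G	A	LRP2	missense		c.403G>A	p.D135N	rs142594441			FALSE		PP	0.999	PP	2	PP	0.00	PP	1	PP	7				
4	3519802	G	A	LRPAP1	missense		c.710G>A	p.R237H	rs760183295			FALSE		PP	0.999	PP	13	-		PP	0.546	NPP	3				
4	3521804	C	T	LRPAP1	missense		c.466C>T	p.H156Y	rs141393177			FALSE		PP	0.996	PP	10	-		PP	0.934	NPP	9				
18	21152041	C	T	NPC1	missense		c.284C>T	p.S95F	rs762610198			FALSE		PP	0.999	PP	23	PP	0.01	NPP	0.022	PP	3				
1	55521765	C	T	PCSK9	missense		c.899C>T	p.A300V				FALSE		PP	0.999	PP	66	PP	0.01	PP	1	PP	7				
20	44530943	C	T	PLTP	missense		c.1138C>T	p.R380W	rs6065903			FALSE		NPP	0.551	PP	68	PP	0.00	PP	1	NPP	6				
8	38005810	G	A	STAR	missense		c.214G>A	p.E72K	rs748942681			FALSE		PP	0.999	PP	65	PP	0.02	NPP	0.358	PP	1				
22	43557122	G	C	TSPO	missense		c.247G>C	p.G83R	rs746919529			FALSE		PP	0.999	PP	1	NPP	0.28	PP	1	PP	4				
22	43557156	C	T	TSPO	missense		c.281C>T	p.A94V	rs142445069			FALSE		PP	0.999	PP	37	NPP	0.36	PP	0.805	PP	5				
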