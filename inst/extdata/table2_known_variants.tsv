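chrom	pos	ref	alt	gene	consequence	splice_distance	chgvs	phgvs	dbsnp_id	gnomad_af	dbsnp_af	hgmd_described	hgmd_phenotype	mt_label	mt_score	snap2_label	snap2_score	sift_label	sift_score	pp2_label	pp2_score	phdsnp_label	phdsnp_score	bdgp_delta	netgene2_delta	assp_delta	cadd_splice
9	107558416	A	G	ABCA1	missense		c.5300A>G	p.Y1767C	rs528270977			TRUE	Reduced total cholesterol														
9	107589238	G	C	ABCA1	missense		c.2328G>C	p.K776N	rs138880920			TRUE	Increased risk of ischemic heart disease														
9	107599376	T	C	ABCA1	missense		c.1196T>C	p.V399A	rs9282543			TRUE	Tangier disease														
9	107646756	C	T	ABCA1	missense		c.254C>T	p.P85L	rs145183203			TRUE	HDL deficiency														
2	44065739	G	C	ABCG5	missense		c.80G>C	p.G27A	rs56204478			TRUE	Hypercholesterolaemia														
2	44101610	T	A	ABCG8	stop_gained		c.1476T>A	p.Y492*	rs370422066			TRUE	Phytosterolaemia														
2	44102301	C	T	ABCG8	missense		c.1505C>T	p.P502L	rs761153163			TRUE	Sitosterolaemia														
19	8436373	C	T	ANGPTL4	missense		c.1006C>T	p.R336C	rs140744493			TRUE	Lower plasma triglyceride level														
11	116691720	A	T	APOA4	missense		c.1054A>T	p.N352Y	rs147577451			TRUE	High triglyceride														
11	116692293	G	T	APOA4	missense		c.481G>T	p.A161S	rs12721043			TRUE	Hyperlipidaemia														
2	21225354	A	G	APOB	missense		c.12940A>G	p.I4314V	rs72654423			TRUE	Hypercholesterolaemia														
2	21228263	C	T	APOB	missense		c.11477C>T	p.T3826M	rs61744153			TRUE	Hypertriglyceridaemia														
2	21228339	T	A	APOB	missense		c.11401T>A	p.S3801T	rs12713540			TRUE	Hypercholesterolaemia														
2	21230828	A	C	APOB	missense		c.8912A>C	p.N2971T	rs72653098			TRUE	Familial hypercholesterolemia														
2	21231278	C	T	APOB	missense		c.8462C>T	p.P2821L	rs72653095			TRUE	Hypocholesterolaemia														
2	21232455	T	A	APOB	missense		c.7285T>A	p.S2429T	rs72653092			TRUE	Hypertriglyceridaemia														
2	21234674	G	A	APOB	missense		c.5066G>A	p.R1689H	rs151009667			TRUE	Hypertriglyceridaemia														
2	21238367	G	A	APOB	missense		c.3383G>A	p.R1128H	rs12713843			TRUE	Hypobetalipoproteinaemia														
2	21238413	G	C	APOB	missense		c.3337G>C	p.D1113H	rs12713844			TRUE	Hypobetalipoproteinaemia														
2	21249682	C	A	APOB	missense		c.2222C>A	p.T741N	rs12714192			TRUE	Dyslipidaemia														
2	21260934	C	T	APOB	missense		c.433C>T	p.P145S	rs6752026			TRUE	Dyslipidaemia														
19	45452024	A	C	APOC2	missense		c.122A>C	p.K41T	rs120074114			TRUE	Apolipoprotein C2 deficiency														
19	45411110	T	C	APOE	missense		c.137T>C	p.L46P	rs769452			TRUE	Hypercholesterolaemia														
17	64210599	T	G	APOH	missense		c.973T>G	p.C325G	rs150652035			TRUE	Apolipoprotein H deficiency														
7	80292426	G	A	CD36	missense		c.550G>A	p.D184N	rs138897347			TRUE	CD36 deficiency														
2	219679730	C	T	CYP27A1	stop_gained		c.1573C>T	p.Q525*	rs374507635			TRUE	Cerebrotendinous xanthomatosis														
19	11217352	G	A	LDLR	missense		c.806G>A	p.G269D	rs143992984			TRUE	Hypercholesterolaemia														
19	11227604	G	A	LDLR	missense		c.1775G>A	p.G592E	rs137929307			TRUE	Hypercholesterolaemia														
19	11233886	C	T	LDLR	missense		c.2177C>T	p.T726I	rs45508991			TRUE	Hypercholesterolaemia														
10	90988005	G	A	LIPA	missense		c.380G>A	p.R127Q	rs544080483			TRUE	Hypercholesterolaemia														
18	47109939	G	A	LIPG	missense		c.1171G>A	p.E391K	rs138438163			TRUE	Higher plasma HDL cholesterol														
18	47109955	A	G	LIPG	missense		c.1187A>G	p.N396S	rs77960347			TRUE	Higher plasma HDL cholesterol														
6	160966559	C	T	LPA	missense		c.5311C>T	p.R1771C	rs139145675			TRUE	Plasminogen deficiency														
6	160969693	A	G	LPA	splice_acceptor	2	c.4974-2A>G		rs143431368			TRUE	Lowered human lipoprotein(a) levels														
2	170042245	A	G	LRP2	missense		c.9613A>G	p.N3205D	rs35734447			TRUE	Hypoplastic left heart syndrome														
14	74953134	G	A	NPC2	missense		c.88G>A	p.V30M	rs151220873			TRUE	Niemann-Pick disease, type C2														
1	109910100	A	G	SORT1	missense		c.370A>G	p.I124V	rs61797119			TRUE	Hypercholesterolaemia														
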