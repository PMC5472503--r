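table	peptides	accession	symbol	description	length	adj_printed	note
human	4	Q8NAP1	GATS	Stromal antigen 3 opposite strand	163	40.8	
human	13	NP_033173	SEC23A	Sec23 homolog A	765	58.8	
human	10	AKI70819	ETFDH	Electron transfer flavoprotein dehydrogenase	617	61.7	
human	9	NP_073150	EBF2	Early B-cell factor 2	575	63.9	
human	5	AAH27322	SLC25A40	Solute carrier family 25 member 40	338	67.6	
human	5	EAX02872	ARMCX4	Armadillo repeat containing, X-linked 4	360	72	
human	4	EAW58763	CD274	CD274 molecule	290	72.5	
human	7	NP_056530	PLA2G3	Phospholipase A2 group III	509	72.7	
human	7	Q6PJ69	TRIM65	Tripartite motif containing 65	517	73.9	
human	4	NP_001103408	C6orf136	Chromosome 6 open reading frame 136	315	78.75	
human	4	CAG46638	HMOX2	Heme oxygenase 2	316	79	
human	7	NP_004877	APBA3	Amyloid beta precursor protein binding family A member 3	575	82.1	
human	9	P19835	CEL	Carboxyl ester lipase	753	83.7	
human	7	NP_001171517	MX1	MX dynamin-like GTPase 1	662	94.6	
human	4	ABQ59031	AMACR	Alpha-methylacyl-CoA racemase	382	95.5	
human	4	NP_003140	STAC	SH3 and cysteine-rich domain	402	100.5	
human	6	NP_001307526	DDX5	DEAD-box helicase 5	614	102.3	
human	4	NP_060708	AGK	Acylglycerol kinase	422	105.5	
human	5	NP_001086	ASIC1	Acid sensing ion channel subunit 1	528	105.6	
human	7	NP_758441	CTAGE1	Cutaneous T-cell lymphoma-associated antigen 1	745	106.4	
human	5	CAG33352	CCT2	Chaperonin containing TCP1 subunit 2	535	107	
human	4	CAG33687	LGMN	Legumain	433	108.3	
human	10	NP_006217	PLCL1	Phospholipase C-like 1	1095	109.5	
human	5	NP_000449	HNF1B	HNF1 homeobox B	557	111.4	
human	4	NP_068712	GABRB3	Gamma-aminobutyric acid type A receptor beta3 subunit	473	118.25	
human	6	P20592	MX2	MX dynamin-like GTPase 2	715	119.7	printed_typo
human	7	NP_060868	CACNA2D3	Calcium voltage-gated channel auxiliary subunit alpha2delta 3	1091	121.2	inconsistent_count
human	5	P30825	SLC7A1	Solute carrier family 7 member 1	629	125.8	
human	4	NP_004557	PFKFB3	6-Phosphofructo-2-kinase/fructose-2,6-biphosphatase 3	520	130	
human	4	XP_011509718	ACOXL	Acyl-CoA oxidase-like	547	136.8	
herv	7	NP_001138567	HHLA1	HERV-H LTR-associating protein 1 precursor	531	75.8	printed_typo
herv	3	P61566	ERVK-24	Endogenous retrovirus group K member 24	588	196	
herv	3	AAY87455	ERVK-6	Env type 1, partial	603	201	
herv	4	AAM81188	HRV-5	Pol protein, partial	863	215.7	
herv	3	P61570	ERVK-25	Endogenous retrovirus group K member 25	661	220.3	
herv	3	P61565	ERVK-21	Endogenous retrovirus group K member 21	698	232.6	printed_truncation
herv	2	P60507	ERVFC1	Endogenous retrovirus group FC1 env polyprotein	584	292	
herv	2	Q14264	ERV3-1	Endogenous retrovirus group 3 member 1	604	302	
herv	2	ABB52637	ERVPABLB-1	Endogenous retrovirus group PABLB member 1	665	332.5	
viral	6	CAD87195	Q70QU7	gp120 protein, human immunodeficiency virus 1	198	33	
viral	3	ADL29714	E0ADF8	Polyprotein GB virus Ccpz	242	80.7	
viral	4	AMB66322	P06764	Envelope glycoprotein I human herpesvirus 2	372	93	
viral	4	AJO72800	P06940	Phosphoprotein canine distemper virus	507	126.8	
viral	3	BAO04373	U6C7N8	RNA-dependent RNA polymerase rodent paramyxovirus	549	183	
viral	3	AJL35076	A0A0C5B2I7	Outer capsid protein porcine rotavirus C	733	244.3	
bacterial	4	WP_033638106	None	Hypothetical protein [Serratia marcescens]	284	71	
bacterial	5	WP_010273745	None	Diaminopimelate aminotransferase [Paenibacillus senegalensis]	397	79.4	
bacterial	3	WP_007050391	B1C8L1	Peptidase M16 [Anaerofustis stercorihominis]	422	140.7	
bacterial	3	WP_004091469	G9Y4S5	Type IV secretion protein Rhs [Hafnia alvei]	644	214.7	
bacterial	3	WP_007483701	I9H2D3	SusC/RagA family TonB-linked outer membrane protein [Bacteroides nordii]	1046	348.7	
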