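activity_id	ec	name	mechanism	res_m2	bond_m1	res_m1	reac_bond	res_p1	bond_p1	res_p2	reactant	families	cazy_class
H1	3.2.1.1	amylose endo-a-1,4-glucosidase	Retaining a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH119,GH13,GH57	GH
H1	3.2.1.1	amylose endo-a-1,4-glucosidase	Inverting (inferred) a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH126	GH
H2	3.2.1.2	amylose exo-a-1,4-glucobiosidase	Inverting a	[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH14	GH
H40	3.2.1.54	cyclomaltodextrin endo-a-1,4-glucosidase	Retaining a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp(cyclic)	H2O	GH13,GH57	GH
H42	3.2.1.57	pullulan exo-a-1,4-isopanosidase	Inverting a	[(aDGlcp-1,4)aDGlcp	1,6	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH49	GH
H45	3.2.1.60	amylose exo-a-1,4-glucotetraosidase	Retaining a	[(aDGlcp)3	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH13	GH
H46	3.2.1.61	mycodextran endo-a-1,4-glucosidase	Unknown a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,3	aDGlcp	H2O	GH87	GH
H75	3.2.1.98	amylose exo-a-1,4-glucohexaosidase	Retaining a	[(aDGlcp)5	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH13	GH
H91	3.2.1.116	amylose exo-a-1,4-glucotriosidase	Retaining a	[(aDGlcp)2	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH13	GH
H107	3.2.1.133	amylose exo-a-1,4-glucobiosidase	Retaining a	[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH13,GH57	GH
H108	3.2.1.135	pullulan exo-a-1,4-panosidase	Retaining a	[(aDGlcp-1,6)aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH13	GH
H112	3.2.1.141	maltotrehalose a-1,4-glucosidase	Retaining a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,1	aDGlcp]	H2O	GH13	GH
H182	3.2.1.-	amylose exo-1,4-glucopentaosidase	Retaining a	[(aDGlcp)4	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH13	GH
H249	3.2.1.-	panose a-1,4-glucosidase	Inverting a	aDGlcp	1,6	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH49	GH
T292	2.4.99.16	starch phosphorylase	Retaining a	[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	aPi	GH13	GH
T309	2.4.1.19	cyclomaltodextrin glucanotransferase	Retaining a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp(cyclic)	a-1,4-aDGlcp	GH13	GH
T311	2.4.1.25	4-a-glucanotransferase	Retaining a	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	a-1,4-aDGlcp	GH13,GH57,GH77	GH
T338	2.4.1.-	a-maltosyltransferase	Retaining a	[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	1,4	aDGlcp	a-1,4-aDGlcp	GH13	GH
H3	3.2.1.3	amylose exo-a-1,4-glucosidase	Inverting a			[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH15	GH
H3	3.2.1.3	amylose exo-a-1,4-glucosidase	Inverting and retaining a			[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	H2O	GH97	GH
H407	3.2.1.-	maltose a-1,4-glucosidase	Retaining a			[aDGlcp	1,4	aDGlcp]			H2O	GH13	GH
T265	2.4.1.8	maltose phosphorylase	Inverting a			[aDGlcp	1,4	DGlcp]			ePi	GH65	GH
T304	2.4.1.4	amylosucrase	Retaining a			[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	a-1,2-bDFruf]	GH13	GH
T318	2.4.1.161	oligosaccharide 4-a-D-glucosyltransferase	Retaining a			[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	a-1,4-aDGlcp	GH13,GH31	GH
T330	2.4.1.-	reuteransucrase a-1,4-glucosyltransferase	Retaining a			[aDGlcp	1,4	aDGlcp	1,2	bDFruf]	a-1,2-bDFruf]	GH70	GH
L345	4.2.2.13	Exo-1,4-a-D-glucan lyase	Retaining a			[aDGlcp	1,4	aDGlcp	1,4	aDGlcp	none	GH31	GH
H500	3.2.1.22	a-galactosidase	Retaining a			[aDGalp	1,X	alcohol			H2O	GH27,GH31,GH36,GH57	GH
H500	3.2.1.22	a-galactosidase	Other a,e			[aDGalp	1,X	alcohol			H2O	GH4	GH
H500	3.2.1.22	a-galactosidase	Inverting and retaining a			[aDGalp	1,X	alcohol			H2O	GH97	GH
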