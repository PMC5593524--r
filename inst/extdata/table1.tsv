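gene	description	fold1	p1	fold2	p2	accession	reference_pmid
ACER2	alkaline ceramidase 2	7	0.0320	2	1.83E-27	NM_001010887	26943039
BTG2	BTG anti-proliferation factor 2	17	0.0382	3	3.47E-44	NM_006763	11814693;8944033
COL17A1	collagen type XVII alpha 1 chain	7	0.0284	3	1.44E-04	NM_000494
CROT	carnitine O-octanoyltransferase	4	1.80E-05	2	5.56E-06	NM_001243745
EDA2R	ectodysplasin A2 receptor	5	2.21E-05	2	1.51E-46	NM_001242310	19543321
FAM198B	family with sequence similarity 198 member B	78	0.0154	2	2.36E-14	NM_016613
GDF15	growth differentiation factor 15	52	0.0036	3	1.35E-12	NM_004864	17276395
GLS2	glutaminase 2	51	0.0438	3	3.41E-21	NM_013267	20351271
GREB1	growth regulation by estrogen in breast cancer 1	13	0.0260	8	8.25E-23	NM_014668
LAMA3	laminin subunit alpha 3	4	0.0405	3	4.88E-08	NM_198129
MICALCL	MICAL C-terminal like	4	0.0457	2	3.88E-10	NM_032867
NPY1R	neuropeptide Y receptor Y1	4	0.0346	5	2.34E-13	NM_000909
SLC27A2	solute carrier family 27 member 2	4	0.0342	3	3.55E-09	NM_003645
SPATA18	spermatogenesis associated 18	45	0.0437	3	1.52E-37	NM_145263	21300779
SYTL2	synaptotagmin like 2	5	0.0337	3	0.0042	NM_032943
TNFRSF10C	TNF receptor superfamily member 10c	162	0.0080	2	6.71E-23	NM_003841	10435597
TSPAN1	tetraspanin 1	8	0.0203	4	5.57E-09	NM_005727
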