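entry_id	preferred_label	synonyms
ENSG:3000001	TP53	p53|tumor protein p53
ENSG:3000002	EGFR	epidermal growth factor receptor|ERBB1
ENSG:3000003	BRCA1	breast cancer type 1 susceptibility protein
ENSG:3000004	BRCA2	breast cancer type 2 susceptibility protein
ENSG:3000005	KRAS
ENSG:3000006	NRAS
ENSG:3000007	BRAF
ENSG:3000008	PIK3CA
ENSG:3000009	PTEN	phosphatase and tensin homolog
ENSG:3000010	AKT1	protein kinase B
ENSG:3000011	MTOR	mechanistic target of rapamycin
ENSG:3000012	MYC	c-myc
ENSG:3000013	RB1	retinoblastoma protein
ENSG:3000014	CDKN2A	p16
ENSG:3000015	CDK4	cyclin-dependent kinase 4
ENSG:3000016	CCND1	cyclin D1
ENSG:3000017	ERBB2	HER2|human epidermal growth factor receptor 2
ENSG:3000018	VEGFA	vascular endothelial growth factor A|VEGF
ENSG:3000019	KDR	VEGFR2|vascular endothelial growth factor receptor 2
ENSG:3000020	ABL1	abelson tyrosine kinase
ENSG:3000021	BCR	breakpoint cluster region protein
ENSG:3000022	JAK2	janus kinase 2
ENSG:3000023	STAT3	signal transducer and activator of transcription 3
ENSG:3000024	NFKB1	nuclear factor kappa B subunit 1
ENSG:3000025	TNF	tumor necrosis factor|TNF-alpha
ENSG:3000026	IL6	interleukin 6|interleukin-6
ENSG:3000027	IL1B	interleukin 1 beta
ENSG:3000028	IFNG	interferon gamma
ENSG:3000029	TGFB1	transforming growth factor beta 1
ENSG:3000030	INS	insulin gene
ENSG:3000031	INSR	insulin receptor
ENSG:3000032	IGF1	insulin-like growth factor 1
ENSG:3000033	LEP	leptin
ENSG:3000034	PPARG	peroxisome proliferator-activated receptor gamma
ENSG:3000035	APOE	apolipoprotein E
ENSG:3000036	APP	amyloid precursor protein
ENSG:3000037	MAPT	tau|microtubule associated protein tau
ENSG:3000038	SNCA	alpha-synuclein
ENSG:3000039	HTT	huntingtin
ENSG:3000040	SOD1	superoxide dismutase 1
ENSG:3000041	CFTR	cystic fibrosis transmembrane conductance regulator
ENSG:3000042	HBB	hemoglobin subunit beta
ENSG:3000043	F8	coagulation factor VIII
ENSG:3000044	LDLR	low density lipoprotein receptor
ENSG:3000045	PCSK9	proprotein convertase subtilisin/kexin type 9
ENSG:3000046	ACE	angiotensin converting enzyme
ENSG:3000047	AGT	angiotensinogen
ENSG:3000048	ESR1	estrogen receptor alpha
ENSG:3000049	AR	androgen receptor
ENSG:3000050	WAS	WASP|wiskott-aldrich syndrome protein
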