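entry_id	preferred_label	synonyms
CHEMBL:2000001	metformin	glucophage|dimethylbiguanide
CHEMBL:2000002	insulin
CHEMBL:2000003	aspirin	acetylsalicylic acid|ASA
CHEMBL:2000004	ibuprofen
CHEMBL:2000005	paracetamol	acetaminophen
CHEMBL:2000006	imatinib	gleevec|STI571
CHEMBL:2000007	gefitinib	iressa
CHEMBL:2000008	erlotinib	tarceva
CHEMBL:2000009	trastuzumab	herceptin
CHEMBL:2000010	bevacizumab	avastin
CHEMBL:2000011	rituximab	rituxan
CHEMBL:2000012	pembrolizumab	keytruda
CHEMBL:2000013	nivolumab	opdivo
CHEMBL:2000014	cisplatin	cis-diamminedichloroplatinum
CHEMBL:2000015	carboplatin
CHEMBL:2000016	paclitaxel	taxol
CHEMBL:2000017	docetaxel	taxotere
CHEMBL:2000018	doxorubicin	adriamycin
CHEMBL:2000019	cyclophosphamide	cytoxan
CHEMBL:2000020	methotrexate	MTX|amethopterin
CHEMBL:2000021	5-fluorouracil	5-FU|fluorouracil
CHEMBL:2000022	gemcitabine	gemzar
CHEMBL:2000023	tamoxifen	nolvadex
CHEMBL:2000024	letrozole	femara
CHEMBL:2000025	olaparib	lynparza
CHEMBL:2000026	vemurafenib	zelboraf
CHEMBL:2000027	dabrafenib	tafinlar
CHEMBL:2000028	sorafenib	nexavar
CHEMBL:2000029	sunitinib	sutent
CHEMBL:2000030	everolimus	afinitor
CHEMBL:2000031	rapamycin	sirolimus
CHEMBL:2000032	statin	HMG-CoA reductase inhibitor
CHEMBL:2000033	atorvastatin	lipitor
CHEMBL:2000034	simvastatin	zocor
CHEMBL:2000035	warfarin	coumadin
CHEMBL:2000036	heparin
CHEMBL:2000037	clopidogrel	plavix
CHEMBL:2000038	lisinopril
CHEMBL:2000039	losartan	cozaar
CHEMBL:2000040	amlodipine	norvasc
CHEMBL:2000041	metoprolol	lopressor
CHEMBL:2000042	omeprazole	prilosec
CHEMBL:2000043	prednisone
CHEMBL:2000044	dexamethasone	decadron
CHEMBL:2000045	azathioprine	imuran
CHEMBL:2000046	infliximab	remicade
CHEMBL:2000047	adalimumab	humira
CHEMBL:2000048	levodopa	L-DOPA
CHEMBL:2000049	donepezil	aricept
CHEMBL:2000050	fluoxetine	prozac
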