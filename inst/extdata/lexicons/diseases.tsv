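entry_id	preferred_label	synonyms
EFO:1000001	type 2 diabetes	T2D|diabetes type 2|non-insulin-dependent diabetes
EFO:1000002	type 1 diabetes	T1D|insulin-dependent diabetes
EFO:1000003	breast cancer	breast carcinoma|mammary cancer
EFO:1000004	lung cancer	lung carcinoma|pulmonary cancer
EFO:1000005	colorectal cancer	CRC|bowel cancer|colon cancer
EFO:1000006	prostate cancer	prostate carcinoma
EFO:1000007	pancreatic cancer	pancreatic carcinoma
EFO:1000008	ovarian cancer	ovarian carcinoma
EFO:1000009	melanoma	malignant melanoma
EFO:1000010	glioblastoma	GBM|glioblastoma multiforme
EFO:1000011	leukemia	leukaemia
EFO:1000012	acute myeloid leukemia	AML|acute myeloid leukaemia
EFO:1000013	chronic myeloid leukemia	CML
EFO:1000014	lymphoma	malignant lymphoma
EFO:1000015	multiple myeloma	MM|plasma cell myeloma
EFO:1000016	alzheimer disease	AD|alzheimers disease|alzheimer's disease
EFO:1000017	parkinson disease	PD|parkinson's disease
EFO:1000018	huntington disease	HD|huntington's disease
EFO:1000019	amyotrophic lateral sclerosis	ALS|lou gehrig disease
EFO:1000020	multiple sclerosis	MS
EFO:1000021	epilepsy	seizure disorder
EFO:1000022	schizophrenia
EFO:1000023	major depressive disorder	MDD|major depression
EFO:1000024	bipolar disorder	BD|manic depression
EFO:1000025	autism spectrum disorder	ASD|autism
EFO:1000026	rheumatoid arthritis	RA
EFO:1000027	osteoarthritis	OA|degenerative arthritis
EFO:1000028	systemic lupus erythematosus	SLE|lupus
EFO:1000029	psoriasis
EFO:1000030	crohn disease	CD|crohn's disease
EFO:1000031	ulcerative colitis	UC
EFO:1000032	celiac disease	coeliac disease|gluten enteropathy
EFO:1000033	asthma	bronchial asthma
EFO:1000034	chronic obstructive pulmonary disease	COPD|chronic obstructive lung disease
EFO:1000035	cystic fibrosis	CF|mucoviscidosis
EFO:1000036	pulmonary fibrosis	lung fibrosis
EFO:1000037	hypertension	high blood pressure
EFO:1000038	coronary artery disease	CAD|coronary heart disease
EFO:1000039	myocardial infarction	MI|heart attack
EFO:1000040	heart failure	cardiac failure
EFO:1000041	atrial fibrillation	AF
EFO:1000042	stroke	cerebrovascular accident
EFO:1000043	obesity	adiposity
EFO:1000044	nonalcoholic fatty liver disease	NAFLD|fatty liver disease
EFO:1000045	cirrhosis	liver cirrhosis
EFO:1000046	hepatitis	liver inflammation
EFO:1000047	chronic kidney disease	CKD|chronic renal disease
EFO:1000048	osteoporosis	bone loss disease
EFO:1000049	anemia	anaemia
EFO:1000050	malaria	plasmodium infection
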