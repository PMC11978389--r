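entry_id	preferred_label	synonyms
TAX:4000001	Homo sapiens	human|humans
TAX:4000002	Mus musculus	mouse|mice
TAX:4000003	Rattus norvegicus	rat|rats
TAX:4000004	Escherichia coli	E. coli
TAX:4000005	Saccharomyces cerevisiae	budding yeast|baker's yeast
TAX:4000006	Drosophila melanogaster	fruit fly
TAX:4000007	Caenorhabditis elegans	C. elegans|nematode
TAX:4000008	Danio rerio	zebrafish
TAX:4000009	Xenopus laevis	african clawed frog
TAX:4000010	Arabidopsis thaliana	thale cress
TAX:4000011	Plasmodium falciparum	malaria parasite
TAX:4000012	Mycobacterium tuberculosis	M. tuberculosis
TAX:4000013	Staphylococcus aureus	S. aureus
TAX:4000014	Streptococcus pneumoniae	pneumococcus
TAX:4000015	Pseudomonas aeruginosa	P. aeruginosa
TAX:4000016	Helicobacter pylori	H. pylori
TAX:4000017	Salmonella enterica
TAX:4000018	Klebsiella pneumoniae
TAX:4000019	Vibrio cholerae	cholera bacterium
TAX:4000020	Bacillus subtilis
TAX:4000021	Candida albicans
TAX:4000022	Aspergillus fumigatus
TAX:4000023	Cryptococcus neoformans
TAX:4000024	Toxoplasma gondii
TAX:4000025	Trypanosoma brucei
TAX:4000026	Leishmania major
TAX:4000027	Schistosoma mansoni
TAX:4000028	human immunodeficiency virus	HIV
TAX:4000029	hepatitis B virus	HBV
TAX:4000030	hepatitis C virus	HCV
TAX:4000031	influenza A virus
TAX:4000032	severe acute respiratory syndrome coronavirus 2	SARS-CoV-2
TAX:4000033	Epstein-Barr virus	EBV
TAX:4000034	human papillomavirus	HPV
TAX:4000035	herpes simplex virus	HSV
TAX:4000036	cytomegalovirus	CMV
TAX:4000037	dengue virus
TAX:4000038	Zika virus
TAX:4000039	Ebola virus
TAX:4000040	rabies virus
TAX:4000041	Gallus gallus	chicken
TAX:4000042	Sus scrofa	pig|swine
TAX:4000043	Bos taurus	cattle|cow
TAX:4000044	Canis lupus familiaris	dog
TAX:4000045	Felis catus	domestic cat
TAX:4000046	Macaca mulatta	rhesus macaque
TAX:4000047	Pan troglodytes	chimpanzee
TAX:4000048	Oryza sativa	rice
TAX:4000049	Zea mays	maize
TAX:4000050	Neurospora crassa
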