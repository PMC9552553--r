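abbreviation	ncbi_taxid	species	source
STRPU	7668	Strongylocentrotus purpuratus	Echinobase
ACAPL	133434	Acanthaster planci	OIST Marine genomics
1529436	1529436	Anneissia japonica	NCBI, PRJNA615663
CIOIN	7719	Ciona intestinalis	Quest For Orthologs 2008
NEMVE	45351	Nematostella vectensis	Quest For Orthologs 2020
BRAFL	7739	Branchiostoma floridae	OIST Marine genomics
AMPQE	400682	Amphimedon queenslandica	Ensembl Metazoa
CRAVI	6565	Crassostrea virginica	NCBI, PRJNA376014
283909	283909	Capitella teleta	NCBI, PRJNA175705
CAEEL	6239	Caenorhabditis elegans	Quest For Orthologs 2020
XENTR	8364	Xenopus tropicalis	Xenbase
CHICK	9031	Gallus gallus	Quest For Orthologs 2020
DROME	7227	Drosophila melanogaster	Quest For Orthologs 2020
SACKO	10224	Saccoglossus kowalevskii	OIST Marine genomics
HUMAN	9606	Homo sapiens	Quest For Orthologs 2020
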