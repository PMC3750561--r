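source	database	n_pathways
KEGG	Kyoto Encyclopedia of Genes and Genomes	186
BIOCARTA	Biocarta	214
PWC	Pathway Commons	656
GO	GeneOntology Biological Processes	808
WIKIPW	WikiPathways	130
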