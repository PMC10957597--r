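go_id	go_name
GO:0006833	Water transport
GO:0009414	Response to water deprivation
GO:0009415	Response to water
GO:0009651	Response to salt stress
GO:0009819	Drought recovery
GO:0015250	Water channel activity
GO:0042538	Hyperosmotic salinity response
GO:0042631	Cellular response to water deprivation
GO:0050891	Multicellular organismal water homeostasis
GO:0071472	Cellular response to salt stress
GO:0080148	Negative regulation of response to water deprivation
GO:1901000	Regulation of response to salt stress
GO:1901001	Negative regulation of response to salt stress
GO:1901002	Positive regulation of response to salt stress
GO:1902584	Positive regulation of response to water deprivation
GO:2000070	Regulation of response to water deprivation
GO:0009409	Response to cold
GO:0015979	Photosynthesis
GO:0006281	DNA repair
GO:0006629	Lipid metabolic process
GO:0009908	Flower development
GO:0006468	Protein phosphorylation
GO:0015995	Chlorophyll biosynthetic process
GO:0048767	Root hair elongation
GO:0009734	Auxin-activated signaling pathway
GO:0050832	Defense response to fungus
GO:0009845	Seed germination
GO:0000398	mRNA splicing via spliceosome
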