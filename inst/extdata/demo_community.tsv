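species	taxon_group	mass_pct	genome_size_mbp	marker_copies	genus
Caenorhabditis elegans	nematode	50	100.2	4	Caenorhabditis
Heterorhabditis bacteriophora	nematode	30	77	3	Heterorhabditis
Steinernema feltiae	nematode	20	91	3	Steinernema
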