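species	taxon_group	mass_pct	genome_size_mbp	marker_copies	genus
Listeria monocytogenes	bacteria	12	2.99	6	Listeria
Pseudomonas aeruginosa	bacteria	12	6.8	4	Pseudomonas
Bacillus subtilis	bacteria	12	4.0	10	Bacillus
Escherichia coli	bacteria	12	4.9	7	Escherichia
Salmonella enterica	bacteria	12	4.8	7	Salmonella
Lactobacillus fermentum	bacteria	12	1.9	5	Lactobacillus
Enterococcus faecalis	bacteria	12	2.8	4	Enterococcus
Staphylococcus aureus	bacteria	12	2.7	6	Staphylococcus
Saccharomyces cerevisiae	yeast	2	12.1	109	Saccharomyces
Cryptococcus neoformans	yeast	2	18.9	60	Cryptococcus
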