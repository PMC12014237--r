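# Demo: 3-species mock community, one probe pair flanking the marker unit.
community: demo_community.tsv
probes: demo_probes.tsv
seed: 20260927
genome_scale: 5.0e-4
unit_length: 1200
n_molecules: 3000
n_genome_copies: 20
background_rate: 0.02
cleavage_prob: 1.0
substitution_rate: 0.0
insertion_rate: 0.0
deletion_rate: 0.0
min_identity: 0.9
abundance_mode: read_count
rank: species
max_mismatches: 2
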