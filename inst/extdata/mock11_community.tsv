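name	copy_number	cell_fraction
Escherichia_coli	7	1
Staphylococcus_aureus	6	1
Pseudomonas_aeruginosa	4	1
Streptococcus_agalactiae	7	1
Corynebacterium_tuberculostearicum	8	1
Enterococcus_faecalis	4	1
Lactobacillus_iners	5	1
Lactobacillus_crispatus	4	1
Atopobium_vaginae	2	1
Gardnerella_vaginalis	2	1
Propionibacterium_acnes	3	1
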