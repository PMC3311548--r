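taxon	method	mean_pct	sd_pct
Escherichia_coli	method1	9.3	2.3
Staphylococcus_aureus	method1	7.5	1.0
Pseudomonas_aeruginosa	method1	2.3	0.9
Streptococcus_agalactiae	method1	15.7	3.1
Corynebacterium_tuberculostearicum	method1	9.4	1.6
Enterococcus_faecalis	method1	6.1	1.5
Lactobacillus_iners	method1	21.5	4.1
Lactobacillus_crispatus	method1	5.2	2.3
Atopobium_vaginae	method1	10.8	2.5
Gardnerella_vaginalis	method1	11.9	1.6
Propionibacterium_acnes	method1	0.3	0.3
Escherichia_coli	method2	8.6	2.0
Staphylococcus_aureus	method2	11.4	1.2
Pseudomonas_aeruginosa	method2	2.7	0.9
Streptococcus_agalactiae	method2	14.8	1.4
Corynebacterium_tuberculostearicum	method2	9.6	2.2
Enterococcus_faecalis	method2	5.9	1.6
Lactobacillus_iners	method2	18.9	3.7
Lactobacillus_crispatus	method2	7.0	2.6
Atopobium_vaginae	method2	8.3	1.7
Gardnerella_vaginalis	method2	11.6	0.9
Propionibacterium_acnes	method2	1.2	0.8
Escherichia_coli	method3	9.5	1.4
Staphylococcus_aureus	method3	5.0	1.1
Pseudomonas_aeruginosa	method3	2.9	1.0
Streptococcus_agalactiae	method3	1.6	1.2
Corynebacterium_tuberculostearicum	method3	5.3	1.2
Enterococcus_faecalis	method3	10.4	3.2
Lactobacillus_iners	method3	45.8	2.3
Lactobacillus_crispatus	method3	2.5	0.9
Atopobium_vaginae	method3	14.6	2.0
Gardnerella_vaginalis	method3	1.8	0.7
Propionibacterium_acnes	method3	0.7	0.3
Escherichia_coli	method4	6.2	1.6
Staphylococcus_aureus	method4	11.4	2.6
Pseudomonas_aeruginosa	method4	1.2	0.7
Streptococcus_agalactiae	method4	19.4	2.8
Corynebacterium_tuberculostearicum	method4	13.8	1.8
Enterococcus_faecalis	method4	7.6	2.5
Lactobacillus_iners	method4	27.6	6.4
Lactobacillus_crispatus	method4	4.0	1.3
Atopobium_vaginae	method4	2.7	1.0
Gardnerella_vaginalis	method4	3.4	1.4
Propionibacterium_acnes	method4	2.7	0.8
Escherichia_coli	method5	3.7	0.9
Staphylococcus_aureus	method5	3.4	0.9
Pseudomonas_aeruginosa	method5	0.9	0.2
Streptococcus_agalactiae	method5	7.1	4.0
Corynebacterium_tuberculostearicum	method5	9.6	2.0
Enterococcus_faecalis	method5	6.3	1.5
Lactobacillus_iners	method5	48.0	9.2
Lactobacillus_crispatus	method5	9.0	3.8
Atopobium_vaginae	method5	5.1	1.1
Gardnerella_vaginalis	method5	5.6	1.6
Propionibacterium_acnes	method5	1.2	0.5
Escherichia_coli	method6	5.8	1.9
Staphylococcus_aureus	method6	4.6	1.2
Pseudomonas_aeruginosa	method6	2.4	0.9
Streptococcus_agalactiae	method6	15.7	3.3
Corynebacterium_tuberculostearicum	method6	15.3	2.5
Enterococcus_faecalis	method6	10.2	2.1
Lactobacillus_iners	method6	37.7	6.3
Lactobacillus_crispatus	method6	3.6	1.5
Atopobium_vaginae	method6	1.9	1.2
Gardnerella_vaginalis	method6	0.5	0.3
Propionibacterium_acnes	method6	2.3	1.6
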