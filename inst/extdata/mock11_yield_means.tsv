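sample	method	concentration
Escherichia_coli	method1	2.96
Escherichia_coli	method2	0.81
Escherichia_coli	method3	0.88
Escherichia_coli	method4	4.26
Escherichia_coli	method5	3.47
Escherichia_coli	method6	1.46
Staphylococcus_aureus	method1	0.85
Staphylococcus_aureus	method2	0.84
Staphylococcus_aureus	method3	0.19
Staphylococcus_aureus	method4	4.81
Staphylococcus_aureus	method5	0.40
Staphylococcus_aureus	method6	0.29
Pseudomonas_aeruginosa	method1	2.38
Pseudomonas_aeruginosa	method2	0.71
Pseudomonas_aeruginosa	method3	0.86
Pseudomonas_aeruginosa	method4	5.39
Pseudomonas_aeruginosa	method5	2.07
Pseudomonas_aeruginosa	method6	1.24
Streptococcus_agalactiae	method1	2.50
Streptococcus_agalactiae	method2	0.75
Streptococcus_agalactiae	method3	0.05
Streptococcus_agalactiae	method4	5.91
Streptococcus_agalactiae	method5	0.46
Streptococcus_agalactiae	method6	0.34
Corynebacterium_tuberculostearicum	method1	1.38
Corynebacterium_tuberculostearicum	method2	0.77
Corynebacterium_tuberculostearicum	method3	0.19
Corynebacterium_tuberculostearicum	method4	4.54
Corynebacterium_tuberculostearicum	method5	0.79
Corynebacterium_tuberculostearicum	method6	0.69
Enterococcus_faecalis	method1	3.12
Enterococcus_faecalis	method2	1.71
Enterococcus_faecalis	method3	0.97
Enterococcus_faecalis	method4	8.33
Enterococcus_faecalis	method5	1.97
Enterococcus_faecalis	method6	1.09
Lactobacillus_iners	method1	3.32
Lactobacillus_iners	method2	1.28
Lactobacillus_iners	method3	1.23
Lactobacillus_iners	method4	6.45
Lactobacillus_iners	method5	3.65
Lactobacillus_iners	method6	1.11
Lactobacillus_crispatus	method1	2.22
Lactobacillus_crispatus	method2	1.24
Lactobacillus_crispatus	method3	0.27
Lactobacillus_crispatus	method4	3.65
Lactobacillus_crispatus	method5	1.16
Lactobacillus_crispatus	method6	0.23
Atopobium_vaginae	method1	1.66
Atopobium_vaginae	method2	0.38
Atopobium_vaginae	method3	0.51
Atopobium_vaginae	method4	1.01
Atopobium_vaginae	method5	0.73
Atopobium_vaginae	method6	0.18
Gardnerella_vaginalis	method1	1.65
Gardnerella_vaginalis	method2	0.58
Gardnerella_vaginalis	method3	0.09
Gardnerella_vaginalis	method4	1.70
Gardnerella_vaginalis	method5	0.62
Gardnerella_vaginalis	method6	0.10
Propionibacterium_acnes	method1	0.35
Propionibacterium_acnes	method2	0.36
Propionibacterium_acnes	method3	0.14
Propionibacterium_acnes	method4	2.20
Propionibacterium_acnes	method5	0.41
Propionibacterium_acnes	method6	0.21
mock	method1	1.52
mock	method2	0.60
mock	method3	0.37
mock	method4	2.77
mock	method5	1.04
mock	method6	0.38
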