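species	group	supergroup	pct_A	pct_C	pct_G	pct_U
Apis mellifera	non_mammal	animal	36.57	13.24	14.93	35.26
Drosophila melanogaster	non_mammal	animal	34.13	17.55	16.45	31.87
Caenorhabditis elegans	non_mammal	animal	26.75	18.15	13.84	41.26
Danio rerio	non_mammal	animal	28.92	16.91	18.72	35.46
Gallus gallus	non_mammal	animal	27.99	17.83	19.88	34.3
Taeniopygia guttata	non_mammal	animal	27.17	19.71	21.48	31.64
Bos taurus	mammal	animal	27.15	20.17	20.59	32.1
Homo sapiens	mammal	animal	26.95	20.41	21.45	31.19
Mus musculus	mammal	animal	26.34	20.96	21.24	31.46
Rattus norvegicus	mammal	animal	26.56	21.03	22.1	30.31
Pongo abelii	mammal	animal	27.87	18.92	21.46	31.75
Arabidopsis thaliana	dicot	plant	27.95	14.59	17.4	40.06
Medicago truncatula	dicot	plant	29.02	13.53	17.59	39.86
Populus trichocarpa	dicot	plant	25.41	16.11	19.73	38.75
Solanum tuberosum	dicot	plant	25.47	15.18	18.56	40.79
Oryza sativa	monocot	plant	25.42	17.77	21.58	35.24
Sorghum bicolor	monocot	plant	24.3	18.22	22.73	34.75
Zea mays	monocot	plant	24.77	18.52	22.47	34.23
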