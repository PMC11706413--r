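rank	rf_species	pca_species
1	Bilophila_unclassified	Rothia_dentocariosa
2	Bifidobacterium_dentium	Bifidobacterium_dentium
3	Ruminococcaceae_bacterium_D16	Scardovia_inopinata
4	Alistipes_putredinis	Scardovia_unclassified
5	Alistipes_indistinctus	Scardovia_wiggsiae
6	Scardovia_wiggsiae	Olsenella_unclassified
7	Gemella_haemolysans	Bacteroides_coprocola
8	Subdoligranulum_unclassified	Bacteroides_sp_3_1_19
9	Peptostreptococcaceae_noname_unclassified	Butyricimonas_synergistica
10	Clostridium_leptum	Parabacteroides_goldsteinii
11	Clostridium_hathewayi	Alistipes_indistinctus
12	Lachnospiraceae_bacterium_3_1_57FAA_CT1	Alistipes_putredinis
13	Clostridium_citroniae	Alistipes_sp_AP11
14	Bilophila_wadsworthia	single_cell_isolate_TM7b
15	Subdoligranulum_variabile	Gemella_haemolysans
16	Bacteroides_coprocola	Lactobacillus_gasseri
17	Parabacteroides_goldsteinii	Lactobacillus_salivarius
18	Lactobacillus_salivarius	Leuconostoc_pseudomesenteroides
19	Clostridium_symbiosum	Streptococcus_pasteurianus
20	Oxalobacter_formigenes	Clostridium_asparagiforme
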