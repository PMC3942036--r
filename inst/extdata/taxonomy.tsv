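species_id	lineage	taxon
Homo_sapiens	Metazoa	Metazoa
Drosophila_melanogaster	Metazoa	Metazoa
Capitella_teleta	Metazoa	Metazoa
Nematostella_vectensis	Metazoa	Metazoa
Trichoplax_adhaerens	Metazoa	Metazoa
Amphimedon_queenslandica	Metazoa	Metazoa
Oscarella_carmela	Metazoa	Metazoa
Mnemiopsis_leidyi	Metazoa	Metazoa
Monosiga_brevicollis	Unicellular_Holozoa	Choanoflagellata
Salpingoeca_rosetta	Unicellular_Holozoa	Choanoflagellata
Capsaspora_owczarzaki	Unicellular_Holozoa	C_owczarzaki
Ministeria_vibrans	Unicellular_Holozoa	M_vibrans
Corallochytrium_limacisporum	Unicellular_Holozoa	Corallochytrium
Sphaeroforma_arctica	Unicellular_Holozoa	Ichthyosporea
Creolimax_fragrantissima	Unicellular_Holozoa	Ichthyosporea
Pirum_gemmata	Unicellular_Holozoa	Ichthyosporea
Abeoforma_whisleri	Unicellular_Holozoa	Ichthyosporea
Amoebidium_parasiticum	Unicellular_Holozoa	Ichthyosporea
Spizellomyces_punctatus	Fungi	Fungi
Batrachochytrium_dendrobatidis	Fungi	Fungi
Allomyces_macrogynus	Fungi	Fungi
Rhizopus_oryzae	Fungi	Fungi
Mucor_circinelloides	Fungi	Fungi
Saccharomyces_cerevisiae	Fungi	Fungi
Schizosaccharomyces_pombe	Fungi	Fungi
Candida_albicans	Fungi	Fungi
Neurospora_crassa	Fungi	Fungi
Aspergillus_nidulans	Fungi	Fungi
Ustilago_maydis	Fungi	Fungi
Cryptococcus_neoformans	Fungi	Fungi
Thecamonas_trahens	Apusozoa	Apusozoa
Acanthamoeba_castellanii	Amoebozoa	Amoebozoa
Dictyostelium_discoideum	Amoebozoa	Amoebozoa
Dictyostelium_purpureum	Amoebozoa	Amoebozoa
Arabidopsis_thaliana	Embryophyta	Embryophyta
Oryza_sativa	Embryophyta	Embryophyta
Zea_mays	Embryophyta	Embryophyta
Selaginella_moellendorffii	Embryophyta	Embryophyta
Physcomitrella_patens	Embryophyta	Embryophyta
Chlamydomonas_reinhardtii	Chlorophyta	Chlorophyta
Volvox_carteri	Chlorophyta	Chlorophyta
Ostreococcus_tauri	Chlorophyta	Chlorophyta
Micromonas_pusilla	Chlorophyta	Chlorophyta
Cyanidioschyzon_merolae	Rhodophyta	Rhodophyta
Chondrus_crispus	Rhodophyta	Rhodophyta
Phytophthora_infestans	Heterokonta	Heterokonta
Ectocarpus_siliculosus	Heterokonta	Heterokonta
Thalassiosira_pseudonana	Heterokonta	Heterokonta
Phaeodactylum_tricornutum	Heterokonta	Heterokonta
Aureococcus_anophagefferens	Heterokonta	Heterokonta
Tetrahymena_thermophila	Alveolata	Alveolata
Paramecium_tetraurelia	Alveolata	Alveolata
Perkinsus_marinus	Alveolata	Alveolata
Plasmodium_falciparum	Alveolata	Alveolata
Toxoplasma_gondii	Alveolata	Alveolata
Bigelowiella_natans	Rhizaria	Rhizaria
Emiliania_huxleyi	Haptophyta	Haptophyta
Guillardia_theta	Cryptophyta	Cryptophyta
Naegleria_gruberi	Excavata	Discoba
Trypanosoma_brucei	Excavata	Discoba
Trichomonas_vaginalis	Excavata	Metamonada
Giardia_lamblia	Excavata	Metamonada
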