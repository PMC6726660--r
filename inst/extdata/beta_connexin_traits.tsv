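taxon	trait	state
Petromyzon_marinus_Cx27.5	motif	?
Amia_calva_Cx31like	motif	?
Chelonia_mydas_Cx26	motif	1
Gekko_japonicus_Cx26	motif	1
Anolis_carolinensis_Cx26	motif	1
Python_bivittatus_Cx26	motif	1
Gallus_gallus_Cx26	motif	1
Taeniopygia_guttata_Cx26	motif	1
Ornithorhynchus_anatinus_Cx26	motif	1
Monodelphis_domestica_Cx26	motif	1
Mus_musculus_Cx26	motif	1
Homo_sapiens_Cx26	motif	1
Chelonia_mydas_Cx30	motif	0
Gekko_japonicus_Cx30	motif	0
Anolis_carolinensis_Cx30	motif	0
Python_bivittatus_Cx30	motif	0
Gallus_gallus_Cx30	motif	0
Taeniopygia_guttata_Cx30	motif	0
Ornithorhynchus_anatinus_Cx30	motif	1
Monodelphis_domestica_Cx30	motif	1
Mus_musculus_Cx30	motif	1
Homo_sapiens_Cx30	motif	1
Callorhinchus_milii_Cx26like	motif	1
Lepisosteus_oculatus_Cx26like	motif	1
Lepisosteus_oculatus_Cx30.3	motif	0
Danio_rerio_Cx30.3	motif	0
Takifugu_rubripes_Cx30.3	motif	0
Oryzias_latipes_Cx30.3	motif	0
Latimeria_chalumnae_Cx26_1	motif	1
Latimeria_chalumnae_Cx26_2	motif	1
Latimeria_chalumnae_Cx26_3	motif	1
Protopterus_annectens_Cx26	motif	1
Neoceratodus_forsteri_Cx26	motif	1
Lepidosiren_paradoxa_Cx26	motif	1
Xenopus_tropicalis_Cx26	motif	1
Rana_catesbeiana_Cx26	motif	1
Callorhinchus_milii_Cx32	motif	1
Rhincodon_typus_Cx32	motif	1
Lepisosteus_oculatus_Cx32	motif	1
Danio_rerio_Cx32	motif	1
Takifugu_rubripes_Cx32	motif	1
Oryzias_latipes_Cx32	motif	1
Latimeria_chalumnae_Cx32	motif	1
Xenopus_tropicalis_Cx32	motif	1
Chelonia_mydas_Cx32	motif	1
Anolis_carolinensis_Cx32	motif	1
Gallus_gallus_Cx32	motif	1
Ornithorhynchus_anatinus_Cx32	motif	1
Monodelphis_domestica_Cx32	motif	1
Mus_musculus_Cx32	motif	1
Homo_sapiens_Cx32	motif	1
Danio_rerio_Cx27.5	motif	1
Danio_rerio_Cx31.7	motif	1
Petromyzon_marinus_Cx27.5	short_tail	0
Amia_calva_Cx31like	short_tail	0
Chelonia_mydas_Cx26	short_tail	1
Gekko_japonicus_Cx26	short_tail	1
Anolis_carolinensis_Cx26	short_tail	1
Python_bivittatus_Cx26	short_tail	1
Gallus_gallus_Cx26	short_tail	1
Taeniopygia_guttata_Cx26	short_tail	1
Ornithorhynchus_anatinus_Cx26	short_tail	1
Monodelphis_domestica_Cx26	short_tail	1
Mus_musculus_Cx26	short_tail	1
Homo_sapiens_Cx26	short_tail	1
Chelonia_mydas_Cx30	short_tail	0
Gekko_japonicus_Cx30	short_tail	0
Anolis_carolinensis_Cx30	short_tail	0
Python_bivittatus_Cx30	short_tail	0
Gallus_gallus_Cx30	short_tail	0
Taeniopygia_guttata_Cx30	short_tail	0
Ornithorhynchus_anatinus_Cx30	short_tail	0
Monodelphis_domestica_Cx30	short_tail	0
Mus_musculus_Cx30	short_tail	0
Homo_sapiens_Cx30	short_tail	0
Callorhinchus_milii_Cx26like	short_tail	0
Lepisosteus_oculatus_Cx26like	short_tail	0
Lepisosteus_oculatus_Cx30.3	short_tail	0
Danio_rerio_Cx30.3	short_tail	0
Takifugu_rubripes_Cx30.3	short_tail	0
Oryzias_latipes_Cx30.3	short_tail	0
Latimeria_chalumnae_Cx26_1	short_tail	1
Latimeria_chalumnae_Cx26_2	short_tail	0
Latimeria_chalumnae_Cx26_3	short_tail	0
Protopterus_annectens_Cx26	short_tail	0
Neoceratodus_forsteri_Cx26	short_tail	0
Lepidosiren_paradoxa_Cx26	short_tail	0
Xenopus_tropicalis_Cx26	short_tail	0
Rana_catesbeiana_Cx26	short_tail	0
Callorhinchus_milii_Cx32	short_tail	0
Rhincodon_typus_Cx32	short_tail	0
Lepisosteus_oculatus_Cx32	short_tail	0
Danio_rerio_Cx32	short_tail	0
Takifugu_rubripes_Cx32	short_tail	0
Oryzias_latipes_Cx32	short_tail	0
Latimeria_chalumnae_Cx32	short_tail	0
Xenopus_tropicalis_Cx32	short_tail	0
Chelonia_mydas_Cx32	short_tail	0
Anolis_carolinensis_Cx32	short_tail	0
Gallus_gallus_Cx32	short_tail	0
Ornithorhynchus_anatinus_Cx32	short_tail	0
Monodelphis_domestica_Cx32	short_tail	0
Mus_musculus_Cx32	short_tail	0
Homo_sapiens_Cx32	short_tail	0
Danio_rerio_Cx27.5	short_tail	0
Danio_rerio_Cx31.7	short_tail	0
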