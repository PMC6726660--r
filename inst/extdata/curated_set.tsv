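taxon	accession	species	gene_label	clade	motif_state	tail_class	source
Petromyzon_marinus_Cx27.5		Petromyzon marinus	Cx27.5	A	?	extended	figure
Amia_calva_Cx31like	GEUG01003334.1	Amia calva	Cx31-like	outgroup	?	extended	methods
Chelonia_mydas_Cx26	XM_007059139.1	Chelonia mydas	Cx26	A	1	short	methods
Gekko_japonicus_Cx26	XM_015429500.1	Gekko japonicus	Cx26	A	1	short	methods
Anolis_carolinensis_Cx26		Anolis carolinensis	Cx26	A	1	short	figure
Python_bivittatus_Cx26		Python bivittatus	Cx26	A	1	short	figure
Gallus_gallus_Cx26		Gallus gallus	Cx26	A	1	short	figure
Taeniopygia_guttata_Cx26		Taeniopygia guttata	Cx26	A	1	short	figure
Ornithorhynchus_anatinus_Cx26		Ornithorhynchus anatinus	Cx26	A	1	short	figure
Monodelphis_domestica_Cx26		Monodelphis domestica	Cx26	A	1	short	figure
Mus_musculus_Cx26		Mus musculus	Cx26	A	1	short	figure
Homo_sapiens_Cx26		Homo sapiens	Cx26	A	1	short	figure
Chelonia_mydas_Cx30		Chelonia mydas	Cx30	A	0	extended	figure
Gekko_japonicus_Cx30		Gekko japonicus	Cx30	A	0	extended	figure
Anolis_carolinensis_Cx30		Anolis carolinensis	Cx30	A	0	extended	figure
Python_bivittatus_Cx30		Python bivittatus	Cx30	A	0	extended	figure
Gallus_gallus_Cx30		Gallus gallus	Cx30	A	0	extended	figure
Taeniopygia_guttata_Cx30		Taeniopygia guttata	Cx30	A	0	extended	figure
Ornithorhynchus_anatinus_Cx30		Ornithorhynchus anatinus	Cx30	A	1	extended	figure
Monodelphis_domestica_Cx30		Monodelphis domestica	Cx30	A	1	extended	figure
Mus_musculus_Cx30		Mus musculus	Cx30	A	1	extended	figure
Homo_sapiens_Cx30		Homo sapiens	Cx30	A	1	extended	figure
Callorhinchus_milii_Cx26like		Callorhinchus milii	Cx26-like	A	1	extended	figure
Lepisosteus_oculatus_Cx26like		Lepisosteus oculatus	Cx26-like	A	1	extended	figure
Lepisosteus_oculatus_Cx30.3		Lepisosteus oculatus	Cx30.3	A	0	extended	figure
Danio_rerio_Cx30.3		Danio rerio	Cx30.3	A	0	extended	figure
Takifugu_rubripes_Cx30.3		Takifugu rubripes	Cx30.3	A	0	extended	figure
Oryzias_latipes_Cx30.3		Oryzias latipes	Cx30.3	A	0	extended	figure
Latimeria_chalumnae_Cx26_1	XM_014493276.1	Latimeria chalumnae	Cx26	A	1	short	methods
Latimeria_chalumnae_Cx26_2	XP_014348762.1	Latimeria chalumnae	Cx26	A	1	extended	methods
Latimeria_chalumnae_Cx26_3	ENSLACG00000007568	Latimeria chalumnae	Cx26	A	1	extended	methods
Protopterus_annectens_Cx26		Protopterus annectens	Cx26	A	1	extended	figure
Neoceratodus_forsteri_Cx26		Neoceratodus forsteri	Cx26	A	1	extended	figure
Lepidosiren_paradoxa_Cx26	GEHZ01053112.1	Lepidosiren paradoxa	Cx26	A	1	extended	methods
Xenopus_tropicalis_Cx26	CR848317.2	Xenopus tropicalis	Cx26	A	1	extended	methods
Rana_catesbeiana_Cx26		Rana catesbeiana	Cx26	A	1	extended	figure
Callorhinchus_milii_Cx32		Callorhinchus milii	Cx32	B	1	extended	figure
Rhincodon_typus_Cx32	XM_020523441.1	Rhincodon typus	Cx32	B	1	extended	methods
Lepisosteus_oculatus_Cx32		Lepisosteus oculatus	Cx32	B	1	extended	figure
Danio_rerio_Cx32	XM_001921588.7	Danio rerio	Cx32	B	1	extended	methods
Takifugu_rubripes_Cx32		Takifugu rubripes	Cx32	B	1	extended	figure
Oryzias_latipes_Cx32		Oryzias latipes	Cx32	B	1	extended	figure
Latimeria_chalumnae_Cx32		Latimeria chalumnae	Cx32	B	1	extended	figure
Xenopus_tropicalis_Cx32		Xenopus tropicalis	Cx32	B	1	extended	figure
Chelonia_mydas_Cx32		Chelonia mydas	Cx32	B	1	extended	figure
Anolis_carolinensis_Cx32		Anolis carolinensis	Cx32	B	1	extended	figure
Gallus_gallus_Cx32		Gallus gallus	Cx32	B	1	extended	figure
Ornithorhynchus_anatinus_Cx32		Ornithorhynchus anatinus	Cx32	B	1	extended	figure
Monodelphis_domestica_Cx32		Monodelphis domestica	Cx32	B	1	extended	figure
Mus_musculus_Cx32		Mus musculus	Cx32	B	1	extended	figure
Homo_sapiens_Cx32		Homo sapiens	Cx32	B	1	extended	figure
Danio_rerio_Cx27.5		Danio rerio	Cx27.5	B	1	extended	figure
Danio_rerio_Cx31.7		Danio rerio	Cx31.7	B	1	extended	figure
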