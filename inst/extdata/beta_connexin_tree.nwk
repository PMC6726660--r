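(Amia_calva_Cx31like,((Petromyzon_marinus_Cx27.5,((((Chelonia_mydas_Cx26,(Gekko_japonicus_Cx26,(Anolis_carolinensis_Cx26,Python_bivittatus_Cx26))),((Gallus_gallus_Cx26,Taeniopygia_guttata_Cx26),(Ornithorhynchus_anatinus_Cx26,(Monodelphis_domestica_Cx26,(Mus_musculus_Cx26,Homo_sapiens_Cx26))))),(((Chelonia_mydas_Cx30,(Gekko_japonicus_Cx30,(Anolis_carolinensis_Cx30,Python_bivittatus_Cx30))),(Gallus_gallus_Cx30,Taeniopygia_guttata_Cx30)),(Ornithorhynchus_anatinus_Cx30,(Monodelphis_domestica_Cx30,(Mus_musculus_Cx30,Homo_sapiens_Cx30))))),(Callorhinchus_milii_Cx26like,(Lepisosteus_oculatus_Cx26like,((Lepisosteus_oculatus_Cx30.3,(Danio_rerio_Cx30.3,(Takifugu_rubripes_Cx30.3,Oryzias_latipes_Cx30.3))),((Latimeria_chalumnae_Cx26_1,(Latimeria_chalumnae_Cx26_2,Latimeria_chalumnae_Cx26_3)),((Protopterus_annectens_Cx26,(Neoceratodus_forsteri_Cx26,Lepidosiren_paradoxa_Cx26)),(Xenopus_tropicalis_Cx26,Rana_catesbeiana_Cx26)))))))),((Callorhinchus_milii_Cx32,Rhincodon_typus_Cx32),(((Lepisosteus_oculatus_Cx32,(Danio_rerio_Cx32,(Takifugu_rubripes_Cx32,Oryzias_latipes_Cx32))),(Danio_rerio_Cx27.5,Danio_rerio_Cx31.7)),(Latimeria_chalumnae_Cx32,(Xenopus_tropicalis_Cx32,((Chelonia_mydas_Cx32,(Anolis_carolinensis_Cx32,Gallus_gallus_Cx32)),(Ornithorhynchus_anatinus_Cx32,(Monodelphis_domestica_Cx32,(Mus_musculus_Cx32,Homo_sapiens_Cx32))))))))));
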