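id	clade	expected_motif_status	expected_hemichannel	expected_gap_junction
cmCx26	cx26_like	canonical	opens_moderate_pco2	NA
gjCx26	cx26_like	canonical	opens_moderate_pco2	NA
xtCx26	cx26_like	canonical	insensitive	NA
lpCx26	cx26_like	canonical	insensitive	closes
lcCx26s	cx26_like	canonical	opens_moderate_pco2	NA
drCx32	cx32	canonical	opens_high_pco2_only	NA
rtCx32	cx32	canonical	opens_high_pco2_only	NA
hCx32syn	cx32	canonical	opens_high_pco2_only	insensitive
xtCx26dPV	cx26_like	canonical	opens_moderate_pco2	NA
hCx26+XenCT	cx26_like	canonical	insensitive	NA
hCx32syn_P228G+P229G+P242G+P268G	cx32	canonical	insensitive	NA
lpCx26_G222P+G238P	cx26_like	canonical	opens_moderate_pco2	NA
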