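individual_id	taxon	site
HA_01	HA	
HA_02	HA	
HA_03	HA	
HA_04	HA	
HA_05	HA	
HA_06	HA	
HA_07	HA	
HA_08	HA	
HA_09	HA	
HA_10	HA	
HA_11	HA	
HA_12	HA	
HB_01	HB	
HB_02	HB	
HB_03	HB	
HB_04	HB	
HB_05	HB	
HB_06	HB	
HB_07	HB	
HB_08	HB	
HB_09	HB	
HB_10	HB	
HB_11	HB	
HB_12	HB	
HAxHB_01	HAxHB	
HAxHB_02	HAxHB	
HAxHB_03	HAxHB	
HAxHB_04	HAxHB	
HAxHB_05	HAxHB	
HAxHB_06	HAxHB	
HAxHB_07	HAxHB	
HAxHB_08	HAxHB	
HAxHB_09	HAxHB	
HAxHB_10	HAxHB	
HAxHB_11	HAxHB	
HAxHB_12	HAxHB	
HAxHX_01	HAxHX	
HAxHX_02	HAxHX	
HAxHX_03	HAxHX	
HAxHX_04	HAxHX	
HAxHX_05	HAxHX	
HAxHX_06	HAxHX	
HAxHX_07	HAxHX	
HAxHX_08	HAxHX	
HAxHX_09	HAxHX	
HAxHX_10	HAxHX	
HBxHX_01	HBxHX	
HBxHX_02	HBxHX	
HBxHX_03	HBxHX	
HBxHX_04	HBxHX	
HBxHX_05	HBxHX	
HBxHX_06	HBxHX	
HBxHX_07	HBxHX	
HBxHX_08	HBxHX	
HBxHX_09	HBxHX	
HBxHX_10	HBxHX	
HX_01	HX	
HX_02	HX	
HX_03	HX	
HX_04	HX	
HX_05	HX	
HX_06	HX	
HX_07	HX	
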