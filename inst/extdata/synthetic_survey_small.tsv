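# seed=7
image_id	species	locality	cultivated	r	g	b
img_001_01	species_001	loc_001_01	TRUE	255	0	133
img_001_02	species_001	loc_001_02	TRUE	255	0	46
img_001_03	species_001	loc_001_03	TRUE	255	0	124
img_001_04	species_001	loc_001_04	FALSE	255	0	24
img_001_05	species_001	loc_001_05	FALSE	255	0	43
img_002_01	species_002	loc_002_01	FALSE	0	0	255
img_002_02	species_002	loc_002_02	FALSE	42	0	255
img_002_03	species_002	loc_002_03	FALSE	36	0	255
img_002_04	species_002	loc_002_04	FALSE	30	0	255
img_002_05	species_002	loc_002_05	FALSE	56	0	255
img_003_01	species_003	loc_003_01	FALSE	12	0	255
img_003_02	species_003	loc_003_02	FALSE	42	0	255
img_003_03	species_003	loc_003_03	FALSE	17	0	255
img_003_04	species_003	loc_003_04	TRUE	84	0	255
img_003_05	species_003	loc_003_05	FALSE	58	0	255
img_004_01	species_004	loc_004_01	TRUE	78	0	255
img_004_02	species_004	loc_004_02	FALSE	97	0	255
img_004_03	species_004	loc_004_03	TRUE	135	0	255
img_004_04	species_004	loc_004_04	FALSE	54	0	255
img_004_05	species_004	loc_004_05	FALSE	72	0	255
img_005_01	species_005	loc_005_01	FALSE	29	0	255
img_005_02	species_005	loc_005_02	FALSE	167	167	167
img_005_03	species_005	loc_005_03	TRUE	13	0	255
img_005_04	species_005	loc_005_04	FALSE	24	0	255
img_005_05	species_005	loc_005_05	FALSE	40	0	255
img_006_01	species_006	loc_006_01	FALSE	24	0	255
img_006_02	species_006	loc_006_02	FALSE	0	6	255
img_006_03	species_006	loc_006_03	FALSE	7	0	255
img_006_04	species_006	loc_006_04	FALSE	0	15	255
img_006_05	species_006	loc_006_05	FALSE	0	26	255
img_007_01	species_007	loc_007_01	FALSE	208	0	255
img_007_02	species_007	loc_007_02	FALSE	214	0	255
img_007_03	species_007	loc_007_03	FALSE	232	0	255
img_007_04	species_007	loc_007_04	FALSE	255	0	242
img_007_05	species_007	loc_007_05	FALSE	255	0	225
img_008_01	species_008	loc_008_01	TRUE	158	0	255
img_008_02	species_008	loc_008_02	FALSE	133	0	255
img_008_03	species_008	loc_008_03	FALSE	118	0	255
img_008_04	species_008	loc_008_04	FALSE	152	0	255
img_008_05	species_008	loc_008_05	FALSE	107	0	255
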