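substrate_volume,plants_per_slab,distance_num_cm,distance_den,row_spacing,plant_density_reported,plants_per_10a_reported
10,3,30,1,150,2.2,2222
10,4,45,2,150,3.0,2963
20,3,100,3,150,2.0,2000
20,4,25,1,150,2.7,2667
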