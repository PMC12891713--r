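cultivar,substrate_volume,plants_per_slab,n_fruits,mean_weight,mean_brix,mean_net,mean_length,mean_diameter,mean_flesh,total_yield,water_productivity
Dalgona,10,3,42,1.22,14.5,1.3,13.7,13.4,40.6,2712,4.1
Dalgona,10,4,42,1.17,14.0,1.2,13.1,13.1,39.6,3466,3.3
Dalgona,20,3,42,1.24,14.1,1.4,13.6,13.4,40.2,2477,3.7
Dalgona,20,4,42,1.18,13.8,1.5,13.3,13.2,35.3,3141,3.1
Hero,10,3,42,1.60,14.3,1.3,15.5,14.3,43.0,3552,5.4
Hero,10,4,42,1.46,13.6,1.2,14.9,13.8,40.1,4339,4.2
Hero,20,3,42,1.61,13.3,1.4,16.0,14.4,41.0,3225,4.8
Hero,20,4,42,1.44,12.8,1.4,15.1,13.8,40.3,3846,3.8
Kingstar,10,3,42,1.68,11.6,1.4,15.6,14.5,39.7,3735,5.7
Kingstar,10,4,42,1.40,11.3,1.6,14.6,14.0,39.3,4161,4.0
Kingstar,20,3,42,1.61,10.4,1.5,15.3,14.4,40.8,3220,4.8
Kingstar,20,4,41,1.54,10.2,1.5,15.0,14.3,40.0,4101,4.1
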