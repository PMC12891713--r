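cultivar,substrate_volume,plants_per_slab,total_yield,water_productivity,fertilizer_cost,substrate_cost,yield_group,wp_group
Dalgona,10,3,2712,4.1,804.8,1085.4,c,a
Dalgona,10,4,3466,3.3,1085.4,1085.4,a,c
Dalgona,20,3,2477,3.7,804.8,1392.9,d,b
Dalgona,20,4,3141,3.1,1085.4,1392.9,b,d
Hero,10,3,3552,5.4,804.8,1085.4,c,a
Hero,10,4,4339,4.2,1085.4,1085.4,a,c
Hero,20,3,3225,4.8,804.8,1392.9,d,b
Hero,20,4,3846,3.8,1085.4,1392.9,b,d
Kingstar,10,3,3735,5.7,804.8,1085.4,a,a
Kingstar,10,4,4161,4.0,1085.4,1085.4,a,c
Kingstar,20,3,3220,4.8,804.8,1392.9,b,b
Kingstar,20,4,4101,4.1,1085.4,1392.9,a,c
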