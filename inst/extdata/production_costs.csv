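substrate_volume,plants_per_slab,substrate,seedlings,labor,maintenance,energy,fertilizer,fixed
10,3,1085.4,2177.56,0,0,0,804.8,3130.2
10,4,1085.4,2903.74,0,0,0,1085.4,3130.2
20,3,1392.9,1960.00,0,0,0,804.8,3130.2
20,4,1392.9,2613.66,0,0,0,1085.4,3130.2
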