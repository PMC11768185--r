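tissue,f_water,f_neutral_lipid,f_phospholipid,f_protein,interstitial_protein_ratio
lung,0.81,0.0030,0.0090,0.008,0.37
brain,0.77,0.0510,0.0565,0.005,0.37
heart,0.76,0.0115,0.0166,0.010,0.37
kidney,0.78,0.0207,0.0162,0.010,0.37
stomach,0.75,0.0488,0.0163,0.010,0.37
small_intestine,0.72,0.0487,0.0163,0.010,0.37
colon_ascendens,0.72,0.0487,0.0163,0.010,0.37
colon_transversum,0.72,0.0487,0.0163,0.010,0.37
colon_descendens,0.72,0.0487,0.0163,0.010,0.37
colon_sigmoid,0.72,0.0487,0.0163,0.010,0.37
liver,0.74,0.0348,0.0252,0.015,0.37
spleen,0.79,0.0077,0.0136,0.010,0.37
pancreas,0.66,0.0403,0.0093,0.010,0.37
muscle,0.79,0.0100,0.0072,0.010,0.37
skin,0.72,0.0284,0.0111,0.008,0.37
bone,0.44,0.0740,0.0011,0.005,0.37
fat,0.18,0.7900,0.0020,0.002,0.37
plasma,0.92,0.0023,0.0013,0.070,0.37
red_cells,0.63,0.0017,0.0029,0.010,0.37
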