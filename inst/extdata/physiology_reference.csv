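sex,organ,volume_L,flow_L_per_min,frac_vascular,frac_interstitial,frac_intracellular,endothelial_ps_per_L,cellular_ps_per_L
male,lung,0.530000000000000,NA,0.2600000,0.1900000,0.550000000000000044409,2,1
male,brain,1.450000000000000,0.7000000000000000,0.0400000,0.1700000,0.789999999999999924505,2,1
male,heart,0.330000000000000,0.2400000000000000,0.1000000,0.1600000,0.739999999999999991118,2,1
male,kidney,0.310000000000000,1.1000000000000001,0.1100000,0.2000000,0.689999999999999946709,2,1
male,stomach,0.150000000000000,0.0400000000000000,0.0800000,0.1700000,0.750000000000000000000,2,1
male,small_intestine,0.640000000000000,0.6000000000000000,0.0900000,0.1700000,0.739999999999999991118,2,1
male,colon_ascendens,0.090000000000000,0.0600000000000000,0.1300000,0.7300000,0.140000000000000013323,2,1
male,colon_transversum,0.090000000000000,0.0600000000000000,0.1300000,0.7300000,0.140000000000000013323,2,1
male,colon_descendens,0.090000000000000,0.0600000000000000,0.1300000,0.7300000,0.140000000000000013323,2,1
male,colon_sigmoid,0.090000000000000,0.0600000000000000,0.1300000,0.7300000,0.140000000000000013323,2,1
male,liver,1.800000000000000,0.3000000000000000,0.1100000,0.1600000,0.729999999999999982236,2,1
male,spleen,0.150000000000000,0.0800000000000000,0.2800000,0.1500000,0.569999999999999951150,2,1
male,pancreas,0.140000000000000,0.0600000000000000,0.1000000,0.1700000,0.729999999999999982236,2,1
male,muscle,29.000000000000000,0.9500000000000000,0.0400000,0.1200000,0.839999999999999968914,2,1
male,skin,3.300000000000000,0.3000000000000000,0.0500000,0.3500000,0.599999999999999977796,2,1
male,bone,10.500000000000000,0.2500000000000000,0.0500000,0.1000000,0.849999999999999977796,2,1
male,fat,18.199999999999999,0.2600000000000000,0.0200000,0.1400000,0.839999999999999968914,2,1
male,venous_blood,3.400000000000000,NA,0.9999998,0.0000001,0.000000100000000005751,2,1
male,arterial_blood,1.900000000000000,NA,0.9999998,0.0000001,0.000000100000000005751,2,1
female,lung,0.435616438356164,NA,0.2600000,0.1900000,0.550000000000000044409,2,1
female,brain,1.191780821917808,0.6042537199346337,0.0400000,0.1700000,0.789999999999999924505,2,1
female,heart,0.271232876712329,0.2071727039775887,0.1000000,0.1600000,0.739999999999999991118,2,1
female,kidney,0.254794520547945,0.9495415598972817,0.1100000,0.2000000,0.689999999999999946709,2,1
female,stomach,0.123287671232877,0.0345287839962648,0.0800000,0.1700000,0.750000000000000000000,2,1
female,small_intestine,0.526027397260274,0.5179317599439718,0.0900000,0.1700000,0.739999999999999991118,2,1
female,colon_ascendens,0.073972602739726,0.0517931759943972,0.1300000,0.7300000,0.140000000000000013323,2,1
female,colon_transversum,0.073972602739726,0.0517931759943972,0.1300000,0.7300000,0.140000000000000013323,2,1
female,colon_descendens,0.073972602739726,0.0517931759943972,0.1300000,0.7300000,0.140000000000000013323,2,1
female,colon_sigmoid,0.073972602739726,0.0517931759943972,0.1300000,0.7300000,0.140000000000000013323,2,1
female,liver,1.479452054794520,0.2589658799719859,0.1100000,0.1600000,0.729999999999999982236,2,1
female,spleen,0.123287671232877,0.0690575679925296,0.2800000,0.1500000,0.569999999999999951150,2,1
female,pancreas,0.115068493150685,0.0517931759943972,0.1000000,0.1700000,0.729999999999999982236,2,1
female,muscle,23.835616438356162,0.8200586199112887,0.0400000,0.1200000,0.839999999999999968914,2,1
female,skin,2.712328767123287,0.2589658799719859,0.0500000,0.3500000,0.599999999999999977796,2,1
female,bone,8.630136986301370,0.2158048999766549,0.0500000,0.1000000,0.849999999999999977796,2,1
female,fat,14.958904109589040,0.2244370959757211,0.0200000,0.1400000,0.839999999999999968914,2,1
female,venous_blood,2.794520547945205,NA,0.9999998,0.0000001,0.000000100000000005751,2,1
female,arterial_blood,1.561643835616438,NA,0.9999998,0.0000001,0.000000100000000005751,2,1
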