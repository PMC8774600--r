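food_category,foodstuff,matrix_kind,n_samples,analyte,detected_rate_pct,min_ng_g,max_ng_g,mean_ng_g,sd_ng_g,gm_ng_g
cereal_1,whole grains - rice flour,solid,59,BP,100,17,108,38,20,34
cereal_1,whole grains - rice flour,solid,59,4-MBP,85,<0.01,12,2.1,1.5,1.9
cereal_1,whole grains - rice flour,solid,59,4-OHBP,5.1,<0.51,33,17,15,12
cereal_1,whole grains - rice flour,solid,59,PBZ,1.7,<0.07,0.94,0.94,,0.94
cereal_2,whole grains - wheat and its products,solid,61,BP,100,14,68,21,8.4,20
cereal_2,whole grains - wheat and its products,solid,61,4-MBP,100,1.2,66,4.2,8.3,2.8
cereal_2,whole grains - wheat and its products,solid,61,PBZ,1.6,<0.05,0.42,0.42,,0.42
cereal_3,whole grains - processed grain products,solid,60,BP,100,22,1084,89,199,47
cereal_3,whole grains - processed grain products,solid,60,4-MBP,100,0.90,12,2.6,1.8,2.3
cereal_3,whole grains - processed grain products,solid,60,4-OHBP,17,<0.05,9.7,4.9,2.2,4.5
cereal_3,whole grains - processed grain products,solid,60,M2BB,8.3,<0.29,17.3,5.3,6.9,2.8
juice_fresh,100% fresh fruit and vegetable juice,liquid,14,BP,100,8.0,29,12,5.4,12
juice_fresh,100% fresh fruit and vegetable juice,liquid,14,4-MBP,100,0.20,0.50,0.30,0.08,0.30
juice_fresh,100% fresh fruit and vegetable juice,liquid,14,M2BB,93,0.44,0.74,0.57,0.09,1.7
juice_fresh,100% fresh fruit and vegetable juice,liquid,14,PBZ,79,0.14,2.3,0.48,0.63,1.5
juice_reconstituted,100% reconstituted fruit and vegetable juice,liquid,63,BP,100,7.3,51,16,9.2,14
juice_reconstituted,100% reconstituted fruit and vegetable juice,liquid,63,4-MBP,87,0.11,1.5,0.20,0.20,0.15
juice_reconstituted,100% reconstituted fruit and vegetable juice,liquid,63,4-OHBP,1.6,0.82,0.82,0.82,,0.05
juice_reconstituted,100% reconstituted fruit and vegetable juice,liquid,63,M2BB,100,0.34,0.84,0.48,0.10,0.47
juice_reconstituted,100% reconstituted fruit and vegetable juice,liquid,63,PBZ,47.6,0.14,1.6,0.38,0.36,1.2
juice_partial,10% or more fruit and vegetable juice,liquid,59,BP,100,5.2,37,13,5.5,12
juice_partial,10% or more fruit and vegetable juice,liquid,59,4-MBP,95,0.12,8.5,0.70,1.4,0.34
juice_partial,10% or more fruit and vegetable juice,liquid,59,M2BB,100,0.37,0.81,0.54,0.11,0.52
juice_partial,10% or more fruit and vegetable juice,liquid,59,PBZ,54,0.14,0.95,0.29,0.19,1.2
milk_full,full-fat milk,liquid,37,BP,100,4.5,16,8.1,2.3,7.8
milk_full,full-fat milk,liquid,37,4-MBP,30,0.34,101,28,32,0.17
milk_full,full-fat milk,liquid,37,4-OHBP,5.4,8.2,12,9.9,2.3,0.14
milk_full,full-fat milk,liquid,37,M2BB,35,0.22,0.46,0.29,0.09,0.14
milk_full,full-fat milk,liquid,37,PBZ,57,0.41,2.6,1.6,0.70,0.22
milk_low,low-fat milk,liquid,9,BP,100,4.2,15,8.2,3.6,7.6
milk_low,low-fat milk,liquid,9,4-MBP,22,21,150,85,91,0.16
milk_low,low-fat milk,liquid,9,4-OHBP,11,9.1,9.1,9.1,,0.17
milk_low,low-fat milk,liquid,9,M2BB,22,0.26,0.29,0.27,0.02,0.13
milk_low,low-fat milk,liquid,9,PBZ,78,0.60,2.3,1.6,0.65,0.55
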