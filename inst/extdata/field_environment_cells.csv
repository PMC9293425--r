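biome,depth,distance,met_C,met_C_se,ws_m3_m3,ws_se,ph,ph_se,c_pct,c_pct_se,n_pct,n_pct_se,cn,cn_se
grassland,0-50mm,2,24.2,1.7,0.35,0.09,4.1,0.1,15.1,4.8,0.89,0.16,16.0,2.5
grassland,0-50mm,10,20.9,1.5,0.31,0.09,4.5,0.1,8.3,1.6,0.64,0.12,13.0,0.0
grassland,0-50mm,30,16.9,0.8,0.42,0.08,4.8,0.1,9.8,2.5,0.78,0.21,12.3,0.3
grassland,50-100mm,2,31.6,2.8,0.35,0.07,4.5,0.1,5.0,1.3,0.37,0.09,13.0,0.6
grassland,50-100mm,10,24.7,2.4,0.30,0.11,4.7,0.1,3.8,1.8,0.29,0.12,12.7,0.7
grassland,50-100mm,30,19.6,0.8,0.20,0.02,4.9,0.1,4.1,1.3,0.29,0.10,15.0,1.0
kanuka,0-50mm,2,35.8,0.3,0.28,0.05,3.1,0.1,6.3,1.3,0.26,0.04,23.7,1.8
kanuka,0-50mm,10,30.8,0.7,0.38,0.07,3.1,0.2,27.9,8.7,0.98,0.10,27.0,5.5
kanuka,0-50mm,30,21.8,0.2,0.40,0.03,3.5,0.4,32.3,5.6,1.45,0.12,22.7,5.2
kanuka,50-100mm,2,48.3,5.1,0.29,0.01,3.4,0.1,1.2,0.1,0.07,0.01,18.5,1.5
kanuka,50-100mm,10,38.8,1.3,0.34,0.05,3.1,0.2,8.4,4.0,0.33,0.10,23.0,3.5
kanuka,50-100mm,30,27.8,0.5,0.21,0.01,4.2,0.4,6.6,2.3,0.42,0.13,14.7,2.2
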