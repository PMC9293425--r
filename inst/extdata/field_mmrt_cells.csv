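biome,depth,distance,dH0_kJ,dH0_kJ_se,dCp_kJ,dCp_kJ_se,t_inf_C,t_inf_C_se,t_opt_C,t_opt_C_se,r25_umol_g_min,r25_se
grassland,0-50mm,2,73.4,3.2,-1.4,0.2,54.2,3.9,82.4,6.6,23.9,6.4
grassland,0-50mm,10,65.8,6.6,-2.6,0.4,34.9,4.6,54.0,6.6,23.8,7.2
grassland,0-50mm,30,68.5,2.3,-1.3,0.1,53.6,6.3,82.5,8.7,40.8,8.9
grassland,50-100mm,2,71.0,4.1,-2.9,0.3,33.7,2.8,51.3,3.8,12.8,1.4
grassland,50-100mm,10,60.0,3.9,-3.2,0.9,31.6,5.4,49.8,9.6,9.4,3.1
grassland,50-100mm,30,49.7,9.8,-3.4,1.7,32.2,6.5,51.5,10.9,8.3,0.7
kanuka,0-50mm,2,65.8,2.1,-1.9,0.4,41.9,6.4,65.4,9.7,16.8,4.7
kanuka,0-50mm,10,75.1,1.7,-1.3,0.2,57.8,6.3,60.1,8.8,35.1,6.4
kanuka,0-50mm,30,77.7,1.7,-1.1,0.2,69.3,8.1,103.1,12.1,53.5,9.1
kanuka,50-100mm,2,38.6,4.5,-1.3,0.4,34.2,10.0,62.6,16.3,4.3,0.8
kanuka,50-100mm,10,61.9,2.4,-1.9,0.2,37.7,1.1,60.1,2.1,11.9,2.1
kanuka,50-100mm,30,59.2,0.7,-2.1,0.2,34.4,1.8,55.4,3.3,15.8,2.1
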