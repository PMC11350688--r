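species,ips,camera_days,mcv,d1,d2,mean_density,se_density,area_km2,optimal_area_km2
B. taxicolor,1685,1238,1.36,0.1738,0.1720,0.1729,0.0134,17314,2404
B. whitei,3152,1594,1.98,0.1429,0.1289,0.1359,0.0264,25006,4156
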