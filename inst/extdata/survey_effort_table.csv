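survey_area,n_stations,elev_min_m,elev_max_m,camera_days,n_photographs,ips_taxicolor,ips_whitei
Bixiri Area,11,2235,3479,2794,12294,832,0
Nibi Area,13,2256,3509,2354,13892,0,648
South Bank of the Yarlung Zangbo River Area,10,582,668,1880,16751,0,0
Uma Mountain Area,6,1751,3145,1374,6942,3,0
Raj Mountain Area,8,1631,2086,1968,8467,0,0
DanGeZhuo Area,3,954,1434,630,684,0,0
GeDang Ditch Area,36,2230,4470,8691,10713,843,0
MeiYuLunBa Area,2,1751,2315,294,5172,0,0
XiGong River Area,6,1124,1590,1080,6532,0,0
DeYang Ditch Area,8,815,1294,1360,6359,7,0
North of the Grand Canyon,31,3650,4700,5580,4578,0,2504
DeErGong Area,80,1750,2890,30500,11980,0,0
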