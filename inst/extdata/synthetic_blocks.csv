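"block","area_km2","elev_min","elev_max","elev_mean","elev_range","mat","map","sr_threat"
"block01",166.1,379,778,578.5,399,24.1,1601,6
"block02",308.1,111,832,471.5,721,24.6,1285,12
"block03",65.8,188,853,520.5,665,24.5,912,8
"block04",76.8,379,1518,948.5,1139,21.3,1892,18
"block05",974.8,453,1864,1158.5,1411,19.9,1918,27
"block06",117.9,329,1189,759,860,22.6,1319,20
"block07",1127.1,388,2157,1272.5,1769,20.1,2590,48
"block08",560.4,242,1626,934,1384,21.1,1722,28
"block09",286.6,669,992,830.5,323,22.2,1221,5
"block10",109.9,549,1749,1149,1200,20.8,2228,18
"block11",131,294,2012,1153,1718,20.4,2589,29
"block12",211.8,172,1327,749.5,1155,23.9,1296,39
"block13",64.4,279,1595,937,1316,21.6,1604,27
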