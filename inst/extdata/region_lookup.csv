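country,region_group,lat,lon
China,Asia,35,105
India,Asia,22,79
Japan,Asia,36,138
Indonesia,Asia,-2,118
Pakistan,Asia,30,70
Thailand,Asia,15,101
Vietnam,Asia,16,106
Bangladesh,Asia,24,90
France,Europe,47,2
Germany,Europe,51,10
Spain,Europe,40,-4
Italy,Europe,42,12
United Kingdom,Europe,54,-2
Ukraine,Europe,49,32
Russia,Europe,58,60
United States,North America,39,-98
Canada,North America,53,-106
Mexico,North America,23,-102
Brazil,Central and South America,-10,-55
Argentina,Central and South America,-34,-64
Chile,Central and South America,-35,-71
Colombia,Central and South America,4,-73
Nigeria,Africa,9,8
Ethiopia,Africa,8,39
South Africa,Africa,-29,25
Egypt,Africa,26,30
Kenya,Africa,0,37
Tanzania,Africa,-6,35
Australia,Australasia,-30,140
New Zealand,Australasia,-42,172
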