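transect_id,lut,length_km,passes
P01,private,30,2
P02,private,32,2
P03,private,34,2
P04,private,36,2
P05,private,38,2
P06,private,40,2
P07,private,30,2
P08,private,42,2
P09,private,33,2
P10,private,33,2
R01,resettlement,40,1
R02,resettlement,38,1
R03,resettlement,36,1
R04,resettlement,35,1
C01,communal,40,1
C02,communal,36,1
C03,communal,34,1
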