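lut,area_km2
private,2530
resettlement,960
communal,984
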