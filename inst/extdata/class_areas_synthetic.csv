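label,area_km2
Humid tropical forest,65198
Other tropical/subtropical,0
Temperate forest,330000
Boreal forest,1124500
Other mid-latitude,150000
Subpolar and polar,875500
Deserts,0
Cold anthropic,60000
Moderate anthropic,40000
Warm anthropic,24802
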