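label,lat,lon,areas
France,46.2,2.2,
Brittany,48.2,-2.9,
Normandy,49.1,0.1,
NW-France,,,Brittany;Normandy
China,35.0,103.0,
Japan,36.0,138.0,
USA,39.0,-98.0,
Canada,56.0,-106.0,
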