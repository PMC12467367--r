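therapist,sessions,I,II,III,IV,V,VI
1,22,0,225,305,445,0,30
2,23,10,35,0,380,295,45
3,11,0,0,60,140,80,0
4,9,0,0,235,235,60,0
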