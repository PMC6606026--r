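population,condition,copies,sd
soluble,G1,91318,10277
dynamic,G1,159437,10277
stable,G1,0,NA
total,G1,250755,NA
soluble,G2,79239,21371
dynamic,G2,104952,26360
stable,G2,107748,26360
total,G2,291939,NA
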