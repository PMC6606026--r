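condition,soluble,dynamic,stable,solubleSd,dynamicSd,stableSd
G1,0.365,0.635,0,0.04,0.04,0
G2,0.27,0.36,0.37,0.07,0.09,0.09
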