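protein,condition,fraction,mean,lo,hi,flag
SMC1,G1,chromatin,61125,47609,74640,1-peptide
SMC1,G1,soluble,NA,NA,NA,missing
SMC3,G1,chromatin,66430,53421,79440,
SMC3,G1,soluble,350228,312360,388095,
SCC1,G1,chromatin,69275,54577,83972,
SCC1,G1,soluble,281140,199837,362444,
STAG1,G1,chromatin,14718,11295,18140,
STAG1,G1,soluble,114355,104557,124152,1-peptide
STAG2,G1,chromatin,44812,37745,51879,2-peptides
STAG2,G1,soluble,144160,131233,157086,1-peptide
SMC1,G2,chromatin,142290,120274,164306,1-peptide
SMC1,G2,soluble,NA,NA,NA,missing
SMC3,G2,chromatin,158478,129846,187111,
SMC3,G2,soluble,622117,557712,686522,
SCC1,G2,chromatin,149500,127373,171627,
SCC1,G2,soluble,356850,270483,443217,
STAG1,G2,chromatin,23017,17947,28087,
STAG1,G2,soluble,120960,119860,122061,1-peptide
STAG2,G2,chromatin,106106,93591,118621,2-peptides
STAG2,G2,soluble,235980,213879,258081,1-peptide
SMC1,prometaphase,chromatin,12461,11497,13425,1-peptide
SMC1,prometaphase,soluble,NA,NA,NA,missing
SMC3,prometaphase,chromatin,14165,12173,16158,
SMC3,prometaphase,soluble,899510,816643,982376,
SCC1,prometaphase,chromatin,13973,10478,17468,
SCC1,prometaphase,soluble,494155,314240,674070,
STAG1,prometaphase,chromatin,2797,1842,3752,
STAG1,prometaphase,soluble,152033,147488,156577,1-peptide
STAG2,prometaphase,chromatin,8112,6863,9361,2-peptides
STAG2,prometaphase,soluble,336062,305203,366922,1-peptide
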