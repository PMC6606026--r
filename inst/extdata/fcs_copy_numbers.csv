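protein,condition,compartment,median,lo68,hi68
SCC1,G1,nucleus_chromatin,250755,160752,387511
SCC1,G1,cytoplasm,10690,2426,28277
SCC1,G2,nucleus_chromatin,291939,228902,547040
SCC1,G2,cytoplasm,6279,2917,9460
SCC1,prometaphase,nucleus_chromatin,52195,35147,72881
SCC1,prometaphase,cytoplasm,203259,138338,303046
STAG1,G1,nucleus_chromatin,50062,26338,95212
STAG1,G1,cytoplasm,1738,419,6726
STAG1,G2,nucleus_chromatin,90712,59923,152640
STAG1,G2,cytoplasm,1048,359,3369
STAG1,prometaphase,nucleus_chromatin,10714,6958,16682
STAG1,prometaphase,cytoplasm,34860,26096,50824
STAG2,G1,nucleus_chromatin,221261,158694,291715
STAG2,G1,cytoplasm,18168,5571,59386
STAG2,G2,nucleus_chromatin,281503,202964,384802
STAG2,G2,cytoplasm,29080,9410,92086
STAG2,prometaphase,nucleus_chromatin,67163,46974,105183
STAG2,prometaphase,cytoplasm,249048,183810,360561
NIPBL,G1,nucleus_chromatin,146764,107180,202180
NIPBL,G1,cytoplasm,7314,3462,13262
NIPBL,G2,nucleus_chromatin,162915,101109,218244
NIPBL,G2,cytoplasm,10537,4819,18812
NIPBL,prometaphase,nucleus_chromatin,32357,22248,44222
NIPBL,prometaphase,cytoplasm,135313,114223,172737
WAPL,G1,nucleus_chromatin,91114,68317,115878
WAPL,G1,cytoplasm,NA,NA,NA
WAPL,G2,nucleus_chromatin,100084,70256,125633
WAPL,G2,cytoplasm,NA,NA,NA
WAPL,prometaphase,nucleus_chromatin,20196,13253,30023
WAPL,prometaphase,cytoplasm,88677,68173,141144
SORORIN,G1,nucleus_chromatin,44396,21054,84541
SORORIN,G1,cytoplasm,1216,363,3551
SORORIN,G2,nucleus_chromatin,104939,40639,163976
SORORIN,G2,cytoplasm,4580,832,27180
SORORIN,prometaphase,nucleus_chromatin,25099,16846,38736
SORORIN,prometaphase,cytoplasm,103462,61909,139749
CTCF,G1,nucleus_chromatin,181157,131295,259610
CTCF,G1,cytoplasm,3671,1192,6294
CTCF,G2,nucleus_chromatin,206494,157309,284756
CTCF,G2,cytoplasm,9708,9256,10160
CTCF,prometaphase,nucleus_chromatin,51898,32725,80216
CTCF,prometaphase,cytoplasm,143505,87355,243766
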