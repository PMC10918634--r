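name,mass
Trypsin autolysis (porcine),842.51
Trypsin autolysis (porcine),1045.56
Trypsin autolysis (porcine),2211.10
Trypsin autolysis (porcine),2283.18
Human keratin,1165.59
Human keratin,1475.79
Human keratin,2383.95
Non-human keratin,1838.90
Non-human keratin,2402.95
CHCA matrix cluster,855.10
CHCA matrix cluster,871.07
Bovine casein alpha-S1,1759.95
Bovine serum albumin,1479.80
Bovine serum albumin,1569.74
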