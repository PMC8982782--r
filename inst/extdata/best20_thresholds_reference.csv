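i,j,description,inattention_mean_mm,attention_mean_mm,gf_mm
3,15,Left jaw angle-outer right brow corner,171.45,146.9,24.55
4,5,Left top jaw-outer right brow corner,168.45,144.06,24.38
4,6,Left top jaw-right brow center,149.17,125.72,23.45
3,6,Left jaw angle-right brow center,158.32,135.01,23.30
4,16,Left top jaw-outer right eye,148.79,126.22,22.56
4,7,Left top jaw-inner right brow corner,122.89,100.99,21.89
4,31,Left top jaw-lower corner right eye,132.7,110.85,21.85
4,30,Left top jaw-upper corner right eye,134.16,112.37,21.79
0,4,Gnathion-outer right brow corner,167.05,145.36,21.69
3,16,Left jaw angle-outer right eye,147.11,125.43,21.67
2,5,Gnathion-outer right brow corner,159.94,138.36,21.58
3,7,Left jaw angle-inner right brow corner,136.43,114.93,21.49
3,31,Left jaw angle-lower corner right eye,131.48,110.45,21.02
3,30,Left jaw angle-upper corner right eye,136.74,115.77,20.96
4,13,Left top jaw-nose lower right boundary,111.63,90.99,20.63
4,12,Left top jaw-nose tip,95.09,74.58,20.51
4,17,Left top jaw-inner right eye,117.02,96.6,20.42
4,11,Left top jaw-nose root,98.58,78.51,20.06
2,6,Gnathion-right brow center,154.53,134.66,19.87
3,17,Left jaw angle-inner right eye,121.38,101.61,19.77
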