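grade,min_sm,pm_low,pm_high,max_alpha
1,0.95,95,105,0.05
2,0.9,90,110,0.1
3,0.85,80,120,0.15
4,0.8,75,125,0.2
5,0.7,70,130,0.25
6,0.6,60,140,0.3
7,0.5,50,150,0.35
8,NA,NA,NA,NA
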