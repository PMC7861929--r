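block,class,se,sp,ppv,acc
morph,N,99.71,93.22,99.17,99.00
morph,S,86.86,99.87,95.42,99.47
morph,V,96.37,99.78,97.05,99.54
morph,F,73.08,99.95,91.94,99.74
inter,N,98.94,68.90,96.29,95.66
inter,S,54.17,99.68,84.50,98.28
inter,V,75.98,99.25,88.46,97.60
inter,F,30.77,99.81,55.81,99.28
amp,N,99.17,18.54,90.86,90.38
amp,S,1.92,99.77,20.69,96.76
amp,V,25.98,99.34,75.00,94.16
amp,F,1.28,99.98,33.33,99.22
morph_inter,N,99.72,92.86,99.13,98.97
morph_inter,S,86.22,99.86,95.05,99.44
morph_inter,V,96.51,99.80,97.32,99.57
morph_inter,F,71.79,99.97,94.92,99.75
morph_amp,N,99.72,93.22,99.17,99.01
morph_amp,S,86.86,99.87,95.42,99.47
morph_amp,V,96.37,99.79,97.18,99.55
morph_amp,F,73.08,99.95,91.94,99.74
inter_amp,N,98.97,82.82,97.92,97.21
inter_amp,S,71.79,99.64,86.49,98.79
inter_amp,V,86.45,99.21,89.32,98.31
inter_amp,F,52.56,99.84,71.93,99.48
morph_inter_amp,N,99.71,93.31,99.19,99.01
morph_inter_amp,S,87.82,99.85,94.81,99.48
morph_inter_amp,V,96.51,99.80,97.32,99.57
morph_inter_amp,F,71.79,99.97,94.92,99.75
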