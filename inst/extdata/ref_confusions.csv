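block,true,n,s,v,f
morph,N,9009,12,12,2
morph,S,40,271,1,0
morph,V,23,0,690,3
morph,F,12,1,8,57
inter,N,8939,26,56,14
inter,S,135,169,8,0
inter,V,162,5,544,5
inter,F,47,0,7,24
amp,N,8960,20,53,2
amp,S,306,6,0,0
amp,V,527,3,186,0
amp,F,68,0,9,1
morph_inter,N,9010,12,11,2
morph_inter,S,42,269,1,0
morph_inter,V,22,2,691,1
morph_inter,F,15,0,7,56
morph_amp,N,9010,12,11,2
morph_amp,S,40,271,1,0
morph_amp,V,23,0,690,3
morph_amp,F,12,1,8,57
inter_amp,N,8942,27,54,12
inter_amp,S,77,224,11,0
inter_amp,V,85,8,619,4
inter_amp,F,28,0,9,41
morph_inter_amp,N,9009,13,11,2
morph_inter_amp,S,37,274,1,0
morph_inter_amp,V,22,2,691,1
morph_inter_amp,F,15,0,7,56
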