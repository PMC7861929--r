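block,accuracy
morph,98.88
inter,95.41
amp,90.26
morph_inter,98.87
morph_amp,98.89
inter_amp,96.89
morph_inter_amp,98.91
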