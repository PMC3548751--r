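study_id,a,b,c,d
SYN1,18,482,35,1465
SYN2,40,960,52,2948
SYN3,9,191,21,779
SYN4,27,573,33,1367
SYN5,0,150,12,638
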