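study_id,beta,variance
SYN1,1.22,0.062
SYN2,1.41,0.038
SYN3,1.18,0.115
SYN4,1.30,0.071
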