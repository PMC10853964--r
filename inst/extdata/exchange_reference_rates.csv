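direction,term,log10_k,ea_kcal
H_to_D,acid,1.62,14
H_to_D,base,10.05,17
H_to_D,water,-1.5,19
H_to_D,pkw,15.05,13.3
D_to_H,acid,1.40,14
D_to_H,base,10.00,17
D_to_H,water,-1.6,19
D_to_H,pkw,14.17,13.3
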