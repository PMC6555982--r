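# Mid-myocardial (M) variant (steep-restitution set, v1): reduced I_Ks
Gto = 0.294
GKs = 0.314
s_endo = 0
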