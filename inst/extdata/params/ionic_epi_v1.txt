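# Epicardial variant (steep-restitution set, v1)
Gto = 0.294
GKs = 0.627
s_endo = 0
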