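# Endocardial variant (steep-restitution set, v1): transmural conductances
# and slow-recovery s-gate kinetics.
Gto = 0.073
GKs = 0.612
s_endo = 1
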