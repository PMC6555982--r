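# Human ventricular ionic model: shared constants (steep-restitution set, v1)
# Units: concentrations mM, time ms, potentials mV, currents A/F,
# conductances nS/pF, volumes uL-scaled as in the reference formulation.
R = 8314.472
T = 310.0
F = 96485.3415
Cm = 0.185
Ko = 5.4
Cao = 2.0
Nao = 140.0
Vc = 0.016404
Vsr = 0.001094
Vss = 0.00005468
Bufc = 0.2
Kbufc = 0.001
Bufsr = 10.0
Kbufsr = 0.3
Bufss = 0.4
Kbufss = 0.00025
Vmaxup = 0.006375
Kup = 0.00025
Vrel = 0.102
k1p = 0.15
k2p = 0.045
k3 = 0.060
k4 = 0.005
ECsr = 1.5
maxsr = 2.5
minsr = 1.0
Vleak = 0.00036
Vxfer = 0.0038
GNa = 14.838
GK1 = 5.405
knaca = 1000.0
KmNai = 87.5
KmCa = 1.38
ksat = 0.1
gamma_ncx = 0.35
alpha_ncx = 2.5
knak = 2.724
KmK = 1.0
KmNa = 40.0
GpCa = 0.1238
KpCa = 0.0005
GpK = 0.0146
GbNa = 0.00029
GbCa = 0.000592
pKNa = 0.03
# steep-restitution modifications (reconstructed set: slowed plateau
# inactivation and deepened fast inactivation of I_CaL, raised I_Kr/I_CaL;
# calibrated against the reported steady-state APD and Ca transients)
GKr = 0.172
GCaL = 0.00008358
tauf_vpos_mult = 2.0
tauf_vneg_mult = 1.0
f2_floor = 0.10
tauf2_vneg_mult = 1.0
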