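# Cross-bridge myofilament model parameters (v1).
# Rates in 1/ms at the reference formulation's base temperature; lengths in um; forces normalized so that
# the optimally activated, optimally overlapped sarcomere produces force 1.
x0 = 0.007
SL0 = 2.2
SLmin = 1.4
SLmax = 2.4
mass = 50.0
viscosity = 3.0
fapp = 0.036904
gapp = 0.017016
gslmod = 6.0
hf = 0.147616
hfmdc = 5.0
hb = 0.029520
gxb = 0.005168
sigmap = 8.0
sigman = 1.0
xPsi = 2.0
# regulatory troponin Ca binding (single high-affinity pool, uM^-1 ms^-1 / ms^-1)
kon = 0.013275
koff = 0.0066375
# cooperative permissiveness: K_np * (TCa_Tot)^7.5 power law via the smooth
# sigmoid sqrt(1/(1+(perm50/TCa)^nperm)), nperm = 15
perm50 = 0.66
nperm = 15.0
knp = 0.2715
kpn = 0.02715
inprmt_max = 100.0
tca_floor = 0.0001
# passive (titin-like) force about rest length
PCon = 0.002
PExp = 10.0
# sarcomere geometry for the thick-filament single-overlap fraction
len_thin = 1.2
len_thick = 1.65
len_hbare = 0.1
# normalized-force -> kPa conversion; calibration constant chosen so the
# mid-myocardial pseudo-isometric peak tension at BCL 1000 ms is ~79 kPa
force_scale = 110.0
# velocity bound for sarcomere shortening/relengthening (um/ms)
max_vel = 0.05
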