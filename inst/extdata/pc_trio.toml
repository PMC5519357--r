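# Synthetic three-PC comparison at 30 C: di-oleoyl (18:1), di-arachidonoyl
# (20:4) and di-DHA (22:6) phosphatidylcholine bilayers of 400 lipids.
# Ground-truth K_A (mN/m), tensionless area (nm2, ~200 lipids per leaflet)
# and phosphate peak-to-peak thickness (nm) follow the usual trend with
# acyl-chain unsaturation: more double bonds -> larger area per lipid,
# thinner bilayer, softer membrane.

[run]
equilibration = 0.25
bin_width = 0.05
d0 = 1.0

[DOPC]
temperature_C = 30
seed = 101
ka = 265
area0 = 134
thickness = 3.75
sigma = 0.35
n_frames = 20000
n_phosphorus = 400
z_frames = 2000

[DAPC]
temperature_C = 30
seed = 102
ka = 250
area0 = 146
thickness = 3.55
sigma = 0.35
n_frames = 20000
n_phosphorus = 400
z_frames = 2000

[DDPC]
temperature_C = 30
seed = 103
ka = 205
area0 = 152
thickness = 3.40
sigma = 0.35
n_frames = 20000
n_phosphorus = 400
z_frames = 2000
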