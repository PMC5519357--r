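# Synthetic three-PE comparison at 30 C, mirroring pc_trio.toml with
# phosphatidylethanolamine head groups: smaller area per lipid and a
# slightly stiffer, thicker bilayer at matched chains.

[run]
equilibration = 0.25
bin_width = 0.05
d0 = 1.0

[DOPE]
temperature_C = 30
seed = 201
ka = 280
area0 = 122
thickness = 3.85
sigma = 0.35
n_frames = 20000
n_phosphorus = 400
z_frames = 2000

[DAPE]
temperature_C = 30
seed = 202
ka = 260
area0 = 132
thickness = 3.65
sigma = 0.35
n_frames = 20000
n_phosphorus = 400
z_frames = 2000

[DDPE]
temperature_C = 30
seed = 203
ka = 215
area0 = 138
thickness = 3.50
sigma = 0.35
n_frames = 20000
n_phosphorus = 400
z_frames = 2000
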