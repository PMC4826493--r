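# Example phantom specification for `mitospot simulate --spec ...`.
# Units: micrometres; see ?phantom_spec for every field and default.
width_um: 1500
height_um: 1500
um_per_px: 2
n_tumor_nuclei: 300
n_positive: 50
cluster_fraction: 0.8
cluster_sd_um: 150
n_lymphocytes: 8
n_pigment: 12
pale_mart1_fraction: 0.05
dark_mart1_fraction: 0.03
noise_sd: 3
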