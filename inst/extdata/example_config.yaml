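# Example simulation config for epitopo (see ?simulation_config)
n_cells: 60
n_layers: 12
tissue_height: 25
nuclear_volume_fraction: 0.55
nuclear_aspect: 2
base_area_cv: 0.3
pixels_per_cell: 150
seed: 42
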