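# Example cellcull run configuration (reduced sizes for a quick smoke run).
# Omitted keys take the package defaults; the full schema is documented in
# ?read_run_config and R/cli.R.
seed: 1
threshold: 0.5
n_train_fields: 1
stride_px: 35
colony_sim:
  field_width_px: 700
  field_height_px: 500
  n_colonies: 3
  colony_radius_um: [90, 140]
  differentiated_fraction: 0.2
cnn:
  epochs: 3
laser:
  power_W: 0.8
  speed_mm_s: 100
  beam_width_um: 50
  line_interval_um: 25
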