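# Example analysis configuration override.  Unlisted keys keep the
# package defaults (see ?default_config); unknown keys are rejected.
stains:
  t_brown: 0.35      # OD threshold, DAB channel
  t_dark: 120        # HSI intensity at or below => dark rescue
detect:
  dilation_radius_um: 2.5
  surround_min: 0.3
hotspot:
  radius_um: 200
  grid_step_um: 10
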