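# Compact demonstration run for `vinescan run --config` / read_run_config():
# a 2-treatment, 1-plot, 3-vine scene scanned at the operational settings.
seed: 7
scene:
  treatments: 2
  plots_per_treatment: 1
  vines_per_plot: 3
sensor:
  fov: 270
  angular_step: 0.5
  scan_rate: 50
  range_noise_sd: 0.012
trajectory:
  speed: 0.5
  gnss_rate: 10
  gnss_noise_sd: 0.02
filter:
  k: 64
  nsigma: 1
  mask_margin: 0.05
alpha:
  alpha: 0.1
biomass_cv: 0.1
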