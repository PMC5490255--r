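# Full simulated experiment: three animals, a nine-step ethyl acetate
# calibration series, and a benzaldehyde-d5 sample carrying a 10^-5.2
# ethyl acetate contamination measured at two dilutions.
mode: simulate
seed: 1
contaminant: ethyl_acetate
reference: ethyl_butyrate
simulation:
  n_animals: 3
  calibration_dilutions_log10: [-10, -9, -8, -7, -6, -5, -4, -3, -2]
  sample_dilutions_log10: [-2, -1]
  true_fraction_log10: -5.2
  noise_sd: 0.006
  gain_sdlog: 0.2
analysis:
  window_halfwidth: 10
  detection_mult: 2
  search_window: 30
  mask_from: metadata
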