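# Default synthetic-study conditions. Sample, source and replicate counts
# follow the reference five-species milk study design; the noise laws and
# their constants are the simulator's own calibration (see the package
# vignette) and live here, not in code.
samples_per_species:
  cow: 103
  goat: 27
  camel: 36
  oat: 34
  soya: 73
sources_per_species:
  cow: 30
  goat: 2
  camel: 2
  oat: 4
  soya: 5
replicate_range: [6, 9]
intensity_sigma: 0.30      # lognormal sigma of per-scan peak intensity noise
mz_jitter_ppm: 10          # Gaussian m/z jitter sd, ppm
background_peaks: 150      # Poisson mean count of background peaks per scan
background_mean_intensity: 800   # mean background peak intensity, counts
tic_sigma: 0.25            # lognormal sigma of the per-scan TIC factor
effect_size: 1.0           # multiplier on marker peak intensities
goat_similarity: 0.75      # cow marker intensity fraction kept in goat milk
source_sigma: 0.10         # lognormal sigma of per-farm, per-lipid marker offsets
marker_scale: 50000        # base marker peak intensity, counts
shared_scale: 100000       # base shared-backbone peak intensity, counts
gl_cross_level: 0.6        # GL marker cross-presence within camel/oat/soya
samples_per_level: 6       # samples per adulteration level
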