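# Default run profile: the full factorial exposure design with the
# package's default host-development, parasitism and parasitoid-trait
# parameters. Analysis settings here use a desk-scale replicate count;
# raise analysis.B for production-scale resampling.
seed: 1
design:
  n_replicates: 54
  age_min: 5
  age_max: 60
  qualities: ["90", "95", "100"]
host_development:
  transition_noise_sd: 0.08
  emergence_delay: 5
  biomass_asymptote: 3
  biomass_rate: 0.15
parasitism:
  superparasitism_rate: 0.01
parasitoid_traits:
  p_female_midpoint: 22
  p_female_scale: 4
  devtime_mean_male: 12.5
  devtime_female_excess: 1
  tibia_plateau_age: 25
analysis:
  B: 200
  tie_method: efron
  reference: "100"
  reference_n_per_cell: 50
io:
  out_dir: parastage_run
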