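{
  "calling": {
    "min_depth": 10,
    "min_quality": 20,
    "het_ab_low": 0.3,
    "het_ab_high": 0.7,
    "hom_ab_max": 0.1,
    "strand_min_fraction": 0.1,
    "strand_check_min_depth": 20,
    "max_other_fraction": 0.1
  },
  "match": {
    "error": { "base_error": 0.01, "sample_error_factor": 2, "freq_floor": 0.001 },
    "rules": { "min_snps": 150, "ln_lr_threshold": 0 }
  },
  "simulate": {
    "mean_depth": 30,
    "depth_dispersion": 1,
    "site_efficiency_sd": 0.8,
    "error_rate": 0.01,
    "damage_rate": 0.02,
    "contamination": 0,
    "mean_quality": 35,
    "quality_sd": 3,
    "nonhuman_fraction": 0.5,
    "duplicate_fraction": 0.3,
    "seed": 1
  },
  "design": {
    "n_autosomal": 2000,
    "n_y": 100,
    "n_samples": 6,
    "sex_ratio": 0.5,
    "n_replicates": 1,
    "n_select": 1000
  },
  "seed": 20260918
}
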