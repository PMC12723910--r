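test_that("build_panel honours marker counts, bounds and determinism", {
  p <- build_panel(5000, 379, freq_uniform(0.05, 0.95), seed = 1)
  expect_s3_class(p, "snp_panel")
  expect_equal(nrow(p), 5379)
  expect_equal(sum(chrom_class_of(p) == "Y"), 379)
  expect_false(any(p$ref == p$alt))
  expect_true(all(p$alt_freq >= 0.05 & p$alt_freq <= 0.95))
  expect_false(anyDuplicated(p$marker_id) > 0)
  # female-targetable markers = total minus Y markers
  expect_equal(nrow(p) - sum(chrom_class_of(p) == "Y"), 5000)
  expect_identical(build_panel(100, 7, seed = 42), build_panel(100, 7, seed = 42))
  expect_error(build_panel(0, 0), "at least one marker")
})

test_that("beta frequency model reproduces its analytic mean", {
  p <- build_panel(1e4, 0, freq_beta(2, 2), seed = 7)
  # beta(2,2): mean 0.5, sd sqrt(1/20); SE of the mean over 1e4 draws
  se <- sqrt(0.05 / 1e4)
  expect_lt(abs(mean(p$alt_freq) - 0.5), 3 * se)
})

test_that("simulate_individuals draws HWE genotypes with correct ploidy", {
  p <- toy_panel(1, alt_freq = 1e-4) # frequency floor ~ 0
  tr <- simulate_individuals(p, 50, seed = 1)
  expect_true(all(tr$genotypes == 0))

  p <- toy_panel(1, alt_freq = 0.5)
  tr <- simulate_individuals(p, 10000, seed = 2)
  het <- mean(tr$genotypes[1, ] == 1)
  expect_lt(abs(het - 0.5), 3 * sqrt(0.25 / 10000)) # binomial SE on 2p(1-p)

  tr1 <- simulate_individuals(p, 1, seed = 3)
  expect_equal(nrow(pair_labels(tr1)), 0)

  # females carry no Y dosage; male Y dosage is haploid
  py <- build_panel(10, 10, seed = 4)
  tr <- simulate_individuals(py, 50, sex_ratio = 0.5, seed = 5)
  ycls <- chrom_class_of(py) == "Y"
  fem <- tr$samples$sex == "female"
  expect_true(all(is.na(tr$genotypes[ycls, fem])))
  expect_true(all(tr$genotypes[ycls, !fem] %in% 0:1))
  expect_true(all(tr$genotypes[!ycls, ] %in% 0:2))
})

test_that("per-marker genotype frequencies recover HWE proportions", {
  p <- build_panel(20, 0, freq_uniform(0.2, 0.8), seed = 11)
  n <- 5000
  tr <- simulate_individuals(p, n, seed = 12)
  for (j in seq_len(nrow(p))) {
    pj <- p$alt_freq[j]
    expected <- c((1 - pj)^2, 2 * pj * (1 - pj), pj^2)
    observed <- tabulate(tr$genotypes[j, ] + 1L, nbins = 3) / n
    se <- sqrt(expected * (1 - expected) / n)
    expect_true(all(abs(observed - expected) <= 4 * se),
                info = sprintf("marker %d deviates from HWE", j))
  }
})

test_that("add_replicates shares genotypes and labels same-donor pairs", {
  p <- toy_panel(50)
  tr <- simulate_individuals(p, 3, seed = 1)
  tr <- add_replicates(tr, "S001", 1)
  pl <- pair_labels(tr)
  expect_equal(pl$relation[pl$sample_a == "S001" & pl$sample_b == "S001-rep1"],
               "same_donor")
  expect_equal(unname(tr$genotypes[, "S001-rep1"]), unname(tr$genotypes[, "S001"]))
  expect_error(add_replicates(tr, "Z999", 1), "not found")

  # n_reps = 2: the three pairs among {A, A-rep*} are all same_donor
  tr2 <- add_replicates(simulate_individuals(p, 2, seed = 2), "S002", 2)
  pl2 <- pair_labels(tr2)
  same <- pl2[pl2$relation == "same_donor", ]
  expect_equal(nrow(same), 3)
  expect_true(all(grepl("^S002", same$sample_a) & grepl("^S002", same$sample_b)))
  # labels symmetric by construction: each unordered pair appears once
  key <- paste(pmin(pl2$sample_a, pl2$sample_b), pmax(pl2$sample_a, pl2$sample_b))
  expect_false(anyDuplicated(key) > 0)
})

test_that("simulate_reads respects conservation, determinism and depth law", {
  p <- build_panel(1000, 50, seed = 21)
  tr <- simulate_individuals(p, 3, seed = 22)
  cfg <- sim_preset("capture_like", seed = 23, damage_rate = 0.05,
                    contamination = 0.05)
  sr <- simulate_reads(tr, p, cfg)
  for (tab in sr$reads) {
    expect_true(all(tab$n_ref + tab$n_alt + tab$n_other == tab$n_fwd + tab$n_rev))
    expect_true(all(tab[, c("n_ref", "n_alt", "n_other")] >= 0))
  }
  expect_identical(sr$reads, simulate_reads(tr, p, cfg)$reads)

  # females get no Y reads
  fem <- which(tr$samples$sex == "female")
  if (length(fem)) {
    ytab <- sr$reads[[fem[1]]][chrom_class_of(p) == "Y", ]
    expect_true(all(ytab$n_fwd + ytab$n_rev == 0))
  }

  # near-zero depth limit
  sr0 <- simulate_reads(tr, p, simulation_config(mean_depth = 1e-9, seed = 1))
  expect_true(all(sapply(sr0$reads, function(t) sum(t$n_fwd + t$n_rev)) == 0))
})

test_that("mean simulated depth matches the configured 0.3x within 3 SE", {
  p <- build_panel(1e5, 0, seed = 31)
  tr <- simulate_individuals(p, 1, seed = 32)
  cfg <- simulation_config(mean_depth = 0.3, depth_dispersion = 1,
                           site_efficiency_sd = 0, seed = 33)
  sr <- simulate_reads(tr, p, cfg)
  d <- sr$reads[[1]]$n_fwd + sr$reads[[1]]$n_rev
  # NB(mu, size): var = mu + mu^2/size = 0.3 + 0.09 = 0.39
  se <- sqrt(0.39 / 1e5)
  expect_lt(abs(mean(d) - 0.3), 3 * se)
})

test_that("noiseless high-depth reads have allelic fractions equal to dosage", {
  p <- toy_panel(500, alt_freq = 0.5)
  tr <- simulate_individuals(p, 2, seed = 41)
  cfg <- simulation_config(mean_depth = 100, depth_dispersion = Inf,
                           error_rate = 0, damage_rate = 0, contamination = 0,
                           site_efficiency_sd = 0, seed = 42)
  sr <- simulate_reads(tr, p, cfg)
  tab <- sr$reads[[1]]
  g <- tr$genotypes[, 1]
  d <- tab$n_ref + tab$n_alt
  covered <- d > 0
  expect_true(all(tab$n_other == 0))
  hom <- covered & g != 1
  expect_true(all(tab$n_alt[hom] == ifelse(g[hom] == 2, d[hom], 0)))
})

test_that("simulation bookkeeping reflects the configured read fractions", {
  p <- build_panel(2000, 0, seed = 51)
  tr <- simulate_individuals(p, 2, seed = 52)
  cfg <- simulation_config(mean_depth = 30, nonhuman_fraction = 0.6,
                           duplicate_fraction = 0.2, seed = 53)
  run <- summarize_run(simulate_reads(tr, p, cfg))
  expect_equal(run$proportion_human, rep(0.4, 2), tolerance = 1e-3)
  expect_equal(run$proportion_duplicates, rep(0.2, 2), tolerance = 1e-3)
  expect_equal(run$proportion_on_target, rep(1, 2))
  expect_lt(abs(mean(run$mean_coverage) - 30), 2)
})
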