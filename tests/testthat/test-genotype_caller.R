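# independent rule-trace oracle: walks the documented rules (1)-(5) literally
oracle_call <- function(site, thr, ploidy) {
  d <- site$n_ref + site$n_alt
  if (d < thr$min_depth) return(c("no_call", "low_depth"))
  if (site$mean_q < thr$min_quality) return(c("no_call", "low_quality"))
  if (site$n_other / (d + site$n_other) > thr$max_other_fraction) {
    return(c("no_call", "excess_other"))
  }
  st <- site$n_fwd + site$n_rev
  if (d >= thr$strand_check_min_depth &&
      min(site$n_fwd, site$n_rev) / st < thr$strand_min_fraction) {
    return(c("no_call", "strand_imbalance"))
  }
  ab <- site$n_alt / d
  if (ploidy == "diploid") {
    if (ab <= thr$hom_ab_max) return(c("hom_ref", "none"))
    if (ab >= 1 - thr$hom_ab_max) return(c("hom_alt", "none"))
    if (ab >= thr$het_ab_low && ab <= thr$het_ab_high) return(c("het", "none"))
  } else {
    if (ab <= thr$hom_ab_max) return(c("hap_ref", "none"))
    if (ab >= 1 - thr$hom_ab_max) return(c("hap_alt", "none"))
  }
  c("no_call", "ambiguous_balance")
}

test_that("call_genotype agrees with the rule-trace oracle on random sites", {
  thr <- calling_thresholds()
  set.seed(101)
  for (i in 1:400) {
    n_ref <- rbinom(1, 30, 0.4)
    n_alt <- rbinom(1, 30, 0.3)
    n_other <- rbinom(1, 4, 0.3)
    tot <- n_ref + n_alt + n_other
    n_fwd <- if (tot > 0) sample(0:tot, 1) else 0L
    site <- make_site(n_ref, n_alt, n_other, mean_q = runif(1, 0, 45),
                      n_fwd = n_fwd, n_rev = tot - n_fwd)
    ploidy <- sample(c("diploid", "haploid"), 1)
    got <- call_genotype(site, thr, ploidy)
    want <- oracle_call(site, thr, ploidy)
    expect_equal(c(got$call, got$no_call_reason), want,
                 info = sprintf("site %d: %s", i, paste(site[1, ], collapse = "/")))
  }
})

test_that("call_genotype reproduces the documented example traces", {
  thr <- calling_thresholds()
  zero <- call_genotype(make_site(), thr, "diploid")
  expect_equal(zero$call, "no_call")
  expect_equal(zero$no_call_reason, "low_depth")

  hom <- call_genotype(make_site(n_ref = 12, n_alt = 0, mean_q = 35,
                                 n_fwd = 6, n_rev = 6), thr, "diploid")
  expect_equal(hom$call, "hom_ref")

  amb <- call_genotype(make_site(n_ref = 9, n_alt = 3, mean_q = 30,
                                 n_fwd = 6, n_rev = 6), thr, "diploid")
  expect_equal(amb$call, "no_call")
  expect_equal(amb$no_call_reason, "ambiguous_balance")

  expect_error(call_genotype(make_site(n_ref = 5, n_fwd = 9, n_rev = 9),
                             thr, "diploid"), "strand")
})

test_that("threshold invariants are validated", {
  expect_error(calling_thresholds(hom_ab_max = 0.4), "hom_ab_max")
  expect_error(calling_thresholds(het_ab_high = 0.95), "hom_ab_max")
  expect_error(calling_thresholds(min_depth = 0), "min_depth")
  expect_s3_class(calling_profile("twist_like", min_depth = 4), "calling_thresholds")
})

test_that("call_sample applies ploidy rules and flags unknown markers", {
  p <- build_panel(40, 10, seed = 61)
  reads <- reads_for_pattern(rep("het", nrow(p)), p$marker_id)
  male <- call_sample(reads, p, calling_thresholds(), sex = "male", sample_id = "M")
  fem <- call_sample(reads, p, calling_thresholds(), sex = "female", sample_id = "F")
  y <- chrom_class_of(p) == "Y"
  # het reads at a haploid Y marker are ambiguous for males, wrong ploidy for females
  expect_true(all(male$calls$call[y] == "no_call"))
  expect_true(all(male$calls$no_call_reason[y] == "ambiguous_balance"))
  expect_true(all(fem$calls$no_call_reason[y] == "wrong_ploidy"))
  expect_true(all(fem$calls$call[!y] == "het"))

  unk <- call_sample(reads, p, calling_thresholds(), sex = "unknown")
  expect_true(all(unk$calls$no_call_reason[y] == "wrong_ploidy"))

  empty <- call_sample(reads[0, ], p, calling_thresholds(), sex = "male")
  expect_true(all(empty$calls$call == "no_call"))
  expect_true(all(empty$calls$no_call_reason[!y] == "low_depth"))

  bad <- rbind(reads, make_site(5, 5, marker_id = "not_in_panel"))
  expect_error(call_sample(bad, p, calling_thresholds(), sex = "male"),
               "not_in_panel")
})

test_that("calling is order independent and monotone in min_depth", {
  p <- build_panel(2000, 0, seed = 71)
  tr <- simulate_individuals(p, 1, seed = 72)
  sr <- simulate_reads(tr, p, sim_preset("capture_like", seed = 73))
  reads <- sr$reads[[1]]
  a <- call_sample(reads, p, calling_thresholds(), sex = "male")
  b <- call_sample(reads[sample(nrow(reads)), ], p, calling_thresholds(), sex = "male")
  expect_identical(a$calls, b$calls)

  typed <- sapply(c(20, 15, 10, 5, 1), function(md) {
    n_typed(call_sample(reads, p, calling_thresholds(min_depth = md), sex = "male"))
  })
  expect_true(all(diff(typed) >= 0)) # relaxing depth never removes calls
})

test_that("consensus keeps only reproducible calls", {
  p <- toy_panel(6)
  a <- callset_from_pattern(c("het", "het", "hom_ref", "no_call", "hom_alt", "het"), p,
                            sample_id = "a1")
  b <- callset_from_pattern(c("het", "hom_ref", "hom_ref", "het", "no_call", "het"), p,
                            sample_id = "a2")
  cons <- consensus_replicates(a, b)
  expect_equal(cons$calls$call, c("het", "no_call", "hom_ref", "no_call", "no_call", "het"))
  expect_equal(cons$calls$no_call_reason[2], "replicate_discordant")
  expect_equal(cons$calls$no_call_reason[4], "low_depth")
  # consensus typed set is a subset of each input's typed set
  typed <- function(cs) cs$calls$marker_id[cs$calls$call != "no_call"]
  expect_true(all(typed(cons) %in% typed(a)))
  expect_true(all(typed(cons) %in% typed(b)))
  # idempotence
  same <- consensus_replicates(a, a)
  expect_identical(same$calls$call, a$calls$call)
  expect_error(consensus_replicates(a, callset_from_pattern("het", toy_panel(1))),
               "same panel")
})
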