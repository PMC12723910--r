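test_that("compare_callsets counts and classifies discordances", {
  p <- toy_panel(10)
  a <- callset_from_pattern(
    c("hom_ref", "het", "hom_alt", "het", "hom_ref", "no_call", "het", "hom_ref", "hom_alt", "het"),
    p, sample_id = "A")
  b <- callset_from_pattern(
    c("hom_ref", "het", "hom_alt", "hom_ref", "hom_alt", "het", "no_call", "hom_ref", "hom_alt", "het"),
    p, sample_id = "B")
  r <- compare_callsets(a, b)
  # overlap: markers typed in both = 8; discordant: m4 (het vs hom: false hom),
  # m5 (hom_ref vs hom_alt: contradictory)
  expect_equal(r$n_overlap, 8)
  expect_equal(r$n_concordant, 6)
  expect_equal(r$n_false_homozygote, 1)
  expect_equal(r$n_contradictory_homozygote, 1)
  expect_equal(r$n_concordant + r$n_false_homozygote + r$n_contradictory_homozygote,
               r$n_overlap)
  # symmetry in every field
  r2 <- compare_callsets(b, a)
  expect_equal(r[c("n_overlap", "n_concordant", "rate", "n_false_homozygote",
                   "n_contradictory_homozygote")],
               r2[c("n_overlap", "n_concordant", "rate", "n_false_homozygote",
                    "n_contradictory_homozygote")])
  # identical call sets: 100%, no discordance
  ri <- compare_callsets(a, a)
  expect_equal(ri$rate, 100)
  expect_equal(ri$n_false_homozygote + ri$n_contradictory_homozygote, 0)
})

test_that("every discordant pair falls in exactly one class", {
  p <- toy_panel(200)
  set.seed(9)
  pat <- function() sample(c("hom_ref", "het", "hom_alt", "no_call"), 200, TRUE)
  for (k in 1:5) {
    a <- callset_from_pattern(pat(), p, sample_id = "A")
    b <- callset_from_pattern(pat(), p, sample_id = "B")
    r <- compare_callsets(a, b)
    expect_equal(r$n_concordant + r$n_false_homozygote + r$n_contradictory_homozygote,
                 r$n_overlap)
  }
})

test_that("haploid vs diploid calls compare by dosage-equivalent allele", {
  ids <- c("m1", "m2", "m3")
  a <- quick_callset(c("hap_ref", "hap_alt", "hap_ref"), "A", marker_ids = ids)
  b <- quick_callset(c("hom_ref", "hom_ref", "het"), "B", marker_ids = ids)
  r <- compare_callsets(a, b)
  expect_equal(r$n_overlap, 3)
  expect_equal(r$n_concordant, 1)      # hap_ref ~ hom_ref
  expect_equal(r$n_contradictory_homozygote, 1) # hap_alt vs hom_ref
  expect_equal(r$n_false_homozygote, 1)         # hap_ref vs het
})

test_that("Y exclusion removes Y markers from the overlap", {
  p <- build_panel(5, 5, seed = 3)
  pat <- rep("hom_ref", 10)
  pat[chrom_class_of(p) == "Y"] <- "hap_ref"
  a <- callset_from_pattern(pat, p, sex = "male", sample_id = "A")
  b <- callset_from_pattern(pat, p, sex = "male", sample_id = "B")
  with_y <- compare_callsets(a, b)
  no_y <- compare_callsets(a, b, exclude_y = TRUE)
  expect_equal(with_y$n_overlap, 10)
  expect_equal(no_y$n_overlap, 5)
  expect_true(no_y$y_excluded)
  # pair overlapping only at Y markers: empty overlap, rate not available
  y_only <- pat
  y_only[chrom_class_of(p) != "Y"] <- "no_call"
  ay <- callset_from_pattern(y_only, p, sex = "male", sample_id = "A")
  by <- callset_from_pattern(y_only, p, sex = "male", sample_id = "B")
  ry <- compare_callsets(ay, by, exclude_y = TRUE)
  expect_equal(ry$n_overlap, 0)
  expect_true(is.na(ry$rate))
  # disjoint namespaces are an error
  expect_error(
    compare_callsets(quick_callset("het", marker_ids = "x1"),
                     quick_callset("het", marker_ids = "x2")),
    "disjoint")
})

test_that("pairwise concordance separates same-donor from unrelated pairs", {
  p <- build_panel(3000, 0, seed = 91)
  tr <- simulate_individuals(p, 4, seed = 92)
  tr <- add_replicates(tr, "S001", 1)
  sr <- simulate_reads(tr, p, sim_preset("capture_like", seed = 93, error_rate = 0.02))
  cs <- lapply(seq_len(5), function(i) {
    call_sample(sr$reads[[i]], p, calling_thresholds(), sex = tr$samples$sex[i],
                sample_id = tr$samples$sample_id[i])
  })
  cm <- pairwise_concordance_matrix(cs)
  expect_equal(nrow(cm), choose(5, 2))
  labels <- pair_labels(tr)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  cm$relation <- labels$relation[match(key(cm$sample_a, cm$sample_b),
                                       key(labels$sample_a, labels$sample_b))]
  expect_gt(mean(cm$rate[cm$relation == "same_donor"]),
            mean(cm$rate[cm$relation == "unrelated"]))
  expect_error(pairwise_concordance_matrix(cs[1]), "at least 2")
})

test_that("accuracy_vs_reference scores typed calls against dosages", {
  p <- toy_panel(6)
  cs <- callset_from_pattern(c("hom_ref", "het", "hom_alt", "no_call", "het", "hom_ref"), p)
  ref <- c(0L, 1L, 2L, 0L, 0L, 0L)
  names(ref) <- p$marker_id
  acc <- accuracy_vs_reference(cs, ref)
  expect_equal(acc$n_typed, 5) # no_call markers never count
  expect_equal(acc$n_correct, 4) # m5 het vs dosage 0 is wrong
  expect_equal(acc$accuracy, 80)
  # typed markers missing from the reference are excluded but counted
  acc2 <- accuracy_vs_reference(cs, ref[1:3])
  expect_equal(acc2$n_typed, 3)
  expect_equal(acc2$n_not_in_reference, 2)
  # nothing evaluable: not-available, not an error
  acc3 <- accuracy_vs_reference(cs, c(x = 1L))
  expect_true(is.na(acc3$accuracy))
})

test_that("aggregate_discordance pools counts, not rates", {
  pair1 <- callset_pair(10, n_false_hom = 1)
  pair2 <- callset_pair(90)
  r1 <- compare_callsets(pair1$a, pair1$b)
  r2 <- compare_callsets(pair2$a, pair2$b)
  pooled <- aggregate_discordance(list(r1, r2))
  expect_equal(pooled$rate, 1) # 1/100, not mean(10%, 0%) = 5%
  expect_equal(aggregate_discordance(list(r1))$rate, 10)
  # data.frame input from the pairwise matrix works too
  df <- pairwise_concordance_matrix(list(pair1$a, pair1$b))
  expect_equal(aggregate_discordance(df)$rate, 10)
})

test_that("consensus concordance beats single replicates on noisy data", {
  p <- build_panel(5000, 0, seed = 101)
  tr <- simulate_individuals(p, 1, seed = 102)
  tr <- add_replicates(tr, "S001", 2)
  cfg <- simulation_config(mean_depth = 15, depth_dispersion = 1,
                           site_efficiency_sd = 0.5, error_rate = 0.05,
                           damage_rate = 0.05, seed = 103)
  sr <- simulate_reads(tr, p, cfg)
  thr <- calling_thresholds()
  cs <- lapply(1:3, function(i) {
    call_sample(sr$reads[[i]], p, thr, sex = tr$samples$sex[i],
                sample_id = tr$samples$sample_id[i])
  })
  a1 <- cs[[1]]; a2 <- cs[[2]]; b <- cs[[3]]
  cons <- consensus_replicates(a1, a2)
  r_cons <- compare_callsets(cons, b)
  r_a1 <- compare_callsets(a1, b)
  r_a2 <- compare_callsets(a2, b)
  expect_gte(r_cons$rate, r_a1$rate)
  expect_gte(r_cons$rate, r_a2$rate)
  expect_lte(r_cons$n_overlap, r_a1$n_overlap)
  expect_lte(r_cons$n_overlap, r_a2$n_overlap)
})
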