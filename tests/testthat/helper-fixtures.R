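# shared fixture builders; everything is generated in code at test time

make_site <- function(n_ref = 0, n_alt = 0, n_other = 0, mean_q = 35,
                      marker_id = "m1", n_fwd = NULL, n_rev = NULL) {
  tot <- n_ref + n_alt + n_other
  if (is.null(n_fwd)) n_fwd <- tot %/% 2L
  if (is.null(n_rev)) n_rev <- tot - n_fwd
  data.frame(marker_id = marker_id, n_ref = n_ref, n_alt = n_alt,
             n_other = n_other, n_fwd = n_fwd, n_rev = n_rev,
             mean_q = mean_q, stringsAsFactors = FALSE)
}

# panel with fixed alt_freq (recycled); n_y markers go on chrY
toy_panel <- function(n_auto, n_y = 0, alt_freq = 0.5, name = "toy") {
  p <- build_panel(n_auto, n_y, seed = 1, name = name)
  p$alt_freq <- rep_len(alt_freq, nrow(p))
  p
}

# reads that deterministically produce a desired call under default thresholds
reads_for_pattern <- function(pattern, marker_ids) {
  n_ref <- integer(length(pattern))
  n_alt <- integer(length(pattern))
  n_ref[pattern %in% c("hom_ref", "hap_ref")] <- 20L
  n_alt[pattern %in% c("hom_alt", "hap_alt")] <- 20L
  het <- pattern == "het"
  n_ref[het] <- 10L
  n_alt[het] <- 10L
  tot <- n_ref + n_alt
  data.frame(marker_id = marker_ids, n_ref = n_ref, n_alt = n_alt,
             n_other = 0L, n_fwd = tot %/% 2L, n_rev = tot - tot %/% 2L,
             mean_q = ifelse(tot > 0, 35, 0), stringsAsFactors = FALSE)
}

# call set produced through the real caller from a desired call pattern
callset_from_pattern <- function(pattern, panel, sex = "male", sample_id = "S") {
  call_sample(reads_for_pattern(pattern, panel$marker_id), panel,
              calling_thresholds(), sex = sex, sample_id = sample_id)
}

# fast direct call-set constructor for large arithmetic fixtures
quick_callset <- function(calls, sample_id = "S", chrom = "chr1",
                          panel_name = "toy", marker_ids = NULL) {
  if (is.null(marker_ids)) marker_ids <- sprintf("m%07d", seq_along(calls))
  df <- data.frame(
    marker_id = marker_ids,
    chrom = rep_len(chrom, length(calls)),
    call = calls,
    no_call_reason = ifelse(calls == "no_call", "low_depth", "none"),
    stringsAsFactors = FALSE
  )
  forensnp:::new_call_set(sample_id, df, NULL, panel_name)
}

# two call sets with a prescribed overlap and discordance breakdown
callset_pair <- function(n_overlap, n_false_hom = 0, n_contra = 0,
                         n_only_a = 0, n_only_b = 0, ids = c("A", "B")) {
  n_conc <- n_overlap - n_false_hom - n_contra
  stopifnot(n_conc >= 0)
  a <- c(rep("hom_ref", n_conc), rep("het", n_false_hom), rep("hom_ref", n_contra),
         rep("hom_alt", n_only_a), rep("no_call", n_only_b))
  b <- c(rep("hom_ref", n_conc), rep("hom_ref", n_false_hom), rep("hom_alt", n_contra),
         rep("no_call", n_only_a), rep("hom_alt", n_only_b))
  list(a = quick_callset(a, ids[1]), b = quick_callset(b, ids[2]))
}

# independent 9-term brute-force oracle for the per-SNP direct-match LR:
# H1 sums over the shared genotype, H2 over all ordered genotype pairs
brute_force_lr <- function(a_ref, a_alt, b_ref, b_alt, p, eps) {
  lik <- function(n_ref, n_alt, g) {
    q <- c(eps, 0.5, 1 - eps)[g + 1]
    q^n_alt * (1 - q)^n_ref
  }
  pri <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  h1 <- 0
  for (g in 0:2) h1 <- h1 + pri[g + 1] * lik(a_ref, a_alt, g) * lik(b_ref, b_alt, g)
  h2 <- 0
  for (ga in 0:2) for (gb in 0:2) {
    h2 <- h2 + pri[ga + 1] * pri[gb + 1] * lik(a_ref, a_alt, ga) * lik(b_ref, b_alt, gb)
  }
  h1 / h2
}

# relation labels for combined multi-assay runs named "<sample>.<assay>"
source_of <- function(run_ids, truth) {
  base <- sub("\\.[a-z]+$", "", run_ids)
  truth$samples$source[match(base, truth$samples$sample_id)]
}
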