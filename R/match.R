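#' Per-read error model for genotype likelihoods
#'
#' The match engine models each informative read at a biallelic site as a
#' Bernoulli draw of the alt allele with probability `eps_eff` for dosage 0,
#' `0.5` for dosage 1 and `1 - eps_eff` for dosage 2, where
#' `eps_eff = min(sample_error_factor * base_error, 0.49)`. The
#' `sample_error_factor` is a multiplicative inflation accounting for
#' sample-specific noise (damage, mapping artifacts) on top of the base
#' sequencing/mapping error. Allele frequencies entering the Hardy-Weinberg
#' priors are clamped to `[freq_floor, 1 - freq_floor]` so monomorphic
#' markers cannot contribute infinite log-LR penalties.
#'
#' @param base_error per-read misread probability, in (0, 0.5). Default 0.01.
#' @param sample_error_factor multiplicative inflation (>= 1). Default 2.
#' @param freq_floor clamp for allele frequencies. Default 0.001.
#' @return an `error_model` list with the derived `eps_eff`.
#' @export
error_model <- function(base_error = 0.01, sample_error_factor = 2,
                        freq_floor = 0.001) {
  em <- list(
    base_error = check_number(base_error, "base_error", 0, 0.5,
                              open_min = TRUE, open_max = TRUE),
    sample_error_factor = check_number(sample_error_factor, "sample_error_factor", 1, Inf),
    freq_floor = check_number(freq_floor, "freq_floor", 0, 0.5, open_max = TRUE)
  )
  em$eps_eff <- min(em$sample_error_factor * em$base_error, 0.49)
  structure(em, class = "error_model")
}

#' Classification rules for direct-match results
#'
#' @param min_snps minimum number of markers covered in both samples for a
#'   conclusive comparison. Default 150, mitigating capture-bias false
#'   positives that concentrate at small marker counts.
#' @param ln_lr_threshold total |ln(LR)| below which the comparison is
#'   inconclusive. Default 0 (sign decides).
#' @return a `match_rules` list.
#' @export
match_rules <- function(min_snps = 150, ln_lr_threshold = 0) {
  structure(
    list(min_snps = check_count(min_snps, "min_snps"),
         ln_lr_threshold = check_number(ln_lr_threshold, "ln_lr_threshold", 0, Inf)),
    class = "match_rules"
  )
}

#' Genotype likelihood from per-allele read depths
#'
#' Unnormalised likelihood of dosage `g` given `n_alt` alt reads out of
#' `n = n_ref + n_alt` informative reads: `q^a * (1-q)^(n-a)` with
#' `q = eps_eff, 0.5, 1 - eps_eff` for `g = 0, 1, 2`. The binomial
#' coefficient is omitted: it cancels in every likelihood ratio, so values
#' are comparable only across genotypes at the same site. With no reads the
#' likelihood is flat (1 for every genotype).
#'
#' @param site list or one-row data.frame with `n_ref` and `n_alt`.
#' @param g dosage, 0, 1 or 2 (vectorised).
#' @param err an [error_model()].
#' @return numeric likelihood(s).
#' @export
#' @examples
#' em <- error_model(0.01, 1)
#' genotype_likelihood(list(n_ref = 0, n_alt = 10), 2, em) # 0.99^10
genotype_likelihood <- function(site, g, err) {
  if (!inherits(err, "error_model")) abort("'err' must be an error_model")
  if (any(!g %in% 0:2)) abort("'g' must be dosage 0, 1 or 2")
  a <- site$n_alt
  n <- site$n_ref + site$n_alt
  if (any(is.na(c(a, n))) || a < 0 || n < a) abort("invalid read counts")
  q <- c(err$eps_eff, 0.5, 1 - err$eps_eff)[g + 1]
  q^a * (1 - q)^(n - a)
}

# log-likelihood matrix (sites x 3 dosages); vectorised, log space
gl_log_matrix <- function(n_alt, n, eps) {
  n_ref <- n - n_alt
  cbind(
    n_alt * log(eps) + n_ref * log1p(-eps),
    n * log(0.5),
    n_alt * log1p(-eps) + n_ref * log(eps)
  )
}

# log(sum(exp(x))) across the 3 columns of a matrix
lse3 <- function(x) {
  m <- pmax(x[, 1], x[, 2], x[, 3])
  m + log(exp(x[, 1] - m) + exp(x[, 2] - m) + exp(x[, 3] - m))
}

# vectorised ln per-SNP LR; exact 0 where either sample has no reads
per_snp_lnlr_vec <- function(a_alt, a_n, b_alt, b_n, p, err) {
  p <- pmin(pmax(p, err$freq_floor), 1 - err$freq_floor)
  lpri <- cbind(2 * log1p(-p), log(2) + log(p) + log1p(-p), 2 * log(p))
  la <- gl_log_matrix(a_alt, a_n, err$eps_eff)
  lb <- gl_log_matrix(b_alt, b_n, err$eps_eff)
  lnlr <- lse3(lpri + la + lb) - lse3(lpri + la) - lse3(lpri + lb)
  lnlr[a_n == 0 | b_n == 0] <- 0
  lnlr
}

#' Likelihood-ratio contribution of one SNP to a direct-match comparison
#'
#' Contrasts H1 "both read sets come from the same donor" against H2 "the
#' donors are different, unrelated individuals" at a single autosomal marker
#' with population alt-allele frequency `p`, using Hardy-Weinberg genotype
#' priors and the [genotype_likelihood()] read model:
#' \deqn{LR = \frac{\sum_g \pi(g) L_a(g) L_b(g)}
#'                 {\left[\sum_g \pi(g) L_a(g)\right]\left[\sum_g \pi(g) L_b(g)\right]}}
#' If either site carries no informative reads the contribution is exactly 1.
#'
#' @param site_a,site_b per-site read counts for the two samples (fields
#'   `n_ref`, `n_alt`).
#' @param p population alt-allele frequency in [0, 1] (clamped by
#'   `err$freq_floor` before use).
#' @param err an [error_model()].
#' @return the LR contribution (a positive number).
#' @export
per_snp_lr <- function(site_a, site_b, p, err) {
  check_number(p, "p", 0, 1)
  exp(per_snp_lnlr_vec(site_a$n_alt, site_a$n_ref + site_a$n_alt,
                       site_b$n_alt, site_b$n_ref + site_b$n_alt, p, err))
}

#' Select autosomal markers for LR calculations
#'
#' Mirrors the reference-data-then-depth selection used for probabilistic
#' identity comparisons: autosomal markers with a defined population
#' frequency are ranked by total read count summed across all samples
#' (descending, ties broken lexicographically by marker id) and the top
#' `n_select` are returned.
#'
#' @param reads named list of per-sample read-count data.frames.
#' @param panel the `snp_panel` (supplies chromosome class and `alt_freq`).
#' @param n_select number of markers to select (>= 1).
#' @return the selected rows of `panel`, in rank order.
#' @export
select_snps <- function(reads, panel, n_select) {
  validate_panel(panel)
  n_select <- check_count(n_select, "n_select", min = 1L)
  if (!is.list(reads) || !length(reads)) abort("'reads' must be a non-empty list of read tables")
  eligible <- chrom_class_of(panel) == "autosome" & !is.na(panel$alt_freq)
  if (!any(eligible)) abort("no autosomal markers with a defined alt_freq")
  total <- numeric(nrow(panel))
  for (tab in reads) {
    idx <- match(panel$marker_id, tab$marker_id)
    hit <- !is.na(idx)
    total[hit] <- total[hit] +
      tab$n_ref[idx[hit]] + tab$n_alt[idx[hit]] + tab$n_other[idx[hit]]
  }
  cand <- which(eligible)
  ord <- cand[order_radix(-total[cand], panel$marker_id[cand])]
  keep <- ord[seq_len(min(n_select, length(ord)))]
  new_snp_panel(as.data.frame(panel)[keep, , drop = FALSE],
                attr(panel, "name") %||% "panel")
}

align_reads <- function(reads, markers, who) {
  idx <- match(markers$marker_id, reads$marker_id)
  if (anyNA(idx)) {
    abort(sprintf("marker subset not covered by read table '%s': %s", who,
                  paste(utils::head(markers$marker_id[is.na(idx)], 5), collapse = ", ")))
  }
  reads[idx, , drop = FALSE]
}

#' Direct-match likelihood ratio for a sample pair
#'
#' Sums per-SNP ln(LR) contributions over the selected markers (log-space
#' throughout, so 50,000-marker panels cannot underflow). Markers without
#' reads in either sample contribute exactly 0. `n_snps_used` counts markers
#' with at least one informative (ref or alt) read in both samples. The
#' comparison is `inconclusive` when `n_snps_used < rules$min_snps` or
#' `|ln_lr| < rules$ln_lr_threshold`; otherwise `match` if `ln_lr > 0`,
#' else `no_match`.
#'
#' @param reads_a,reads_b read-count data.frames for the two samples.
#' @param markers marker subset from [select_snps()] (or any `snp_panel`
#'   subset with `marker_id` and `alt_freq`).
#' @param err an [error_model()].
#' @param rules a [match_rules()] object.
#' @param keep_per_snp retain the per-marker ln contributions?
#' @param sample_a,sample_b sample ids recorded in the result.
#' @return a `match_result`: `sample_a`, `sample_b`, `ln_lr`, `n_snps_used`,
#'   `classification` and optionally `per_snp` (named numeric vector).
#' @export
direct_match <- function(reads_a, reads_b, markers, err = error_model(),
                         rules = match_rules(), keep_per_snp = FALSE,
                         sample_a = "A", sample_b = "B") {
  if (!inherits(err, "error_model")) abort("'err' must be an error_model")
  if (!inherits(rules, "match_rules")) abort("'rules' must be match_rules")
  if (is.null(markers$alt_freq)) abort("'markers' must carry an alt_freq column")
  if (any(is.na(markers$alt_freq))) abort("selected markers must all have a defined alt_freq")
  a <- align_reads(reads_a, markers, sample_a)
  b <- align_reads(reads_b, markers, sample_b)
  a_n <- a$n_ref + a$n_alt
  b_n <- b$n_ref + b$n_alt
  lnlr <- per_snp_lnlr_vec(a$n_alt, a_n, b$n_alt, b_n, markers$alt_freq, err)
  ln_lr <- sum(lnlr)
  n_used <- sum(a_n >= 1 & b_n >= 1)
  classification <- if (n_used < rules$min_snps || abs(ln_lr) < rules$ln_lr_threshold) {
    "inconclusive"
  } else if (ln_lr > 0) "match" else "no_match"
  res <- list(sample_a = sample_a, sample_b = sample_b, ln_lr = ln_lr,
              n_snps_used = n_used, classification = classification)
  if (keep_per_snp) res$per_snp <- stats::setNames(lnlr, markers$marker_id)
  structure(res, class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %s vs %s: ln(LR) = %.2f over %d SNPs -> %s\n",
              x$sample_a, x$sample_b, x$ln_lr, x$n_snps_used, x$classification))
  invisible(x)
}

#' Direct-match comparisons for all unordered sample pairs
#'
#' @param reads named list (>= 2 entries) of per-sample read-count tables.
#' @param markers marker subset from [select_snps()].
#' @param err an [error_model()].
#' @param rules a [match_rules()] object.
#' @return data.frame with one row per unordered pair: `sample_a`,
#'   `sample_b`, `ln_lr`, `n_snps_used`, `classification`. The implied ln(LR)
#'   matrix is symmetric because each pair is computed once.
#' @export
pairwise_match_matrix <- function(reads, markers, err = error_model(),
                                  rules = match_rules()) {
  if (!is.list(reads) || length(reads) < 2L) abort("need at least 2 samples")
  ids <- names(reads)
  if (is.null(ids) || anyDuplicated(ids)) abort("'reads' must be a uniquely named list")
  idx <- utils::combn(length(ids), 2L)
  out <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    r <- direct_match(reads[[i]], reads[[j]], markers, err, rules,
                      sample_a = ids[i], sample_b = ids[j])
    out[[k]] <- data.frame(sample_a = r$sample_a, sample_b = r$sample_b,
                           ln_lr = r$ln_lr, n_snps_used = r$n_snps_used,
                           classification = r$classification,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
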