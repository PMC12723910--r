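new_call_rate_result <- function(sample_id, n_typed, n_targetable) {
  rate <- if (n_targetable > 0) 100 * n_typed / n_targetable else NA_real_
  structure(
    list(sample_id = sample_id, n_typed = n_typed,
         n_targetable = n_targetable, rate = rate,
         rate_reported = round_half_up(rate, 1)),
    class = "call_rate_result"
  )
}

#' Call rate from typed / targetable marker counts
#'
#' The arithmetic core of [call_rate()], exposed so call rates can be
#' computed directly from reported counts (e.g. published per-sample typed
#' SNP counts) without materialising a call set.
#'
#' @param n_typed number of typed markers.
#' @param n_targetable sex-adjusted number of targetable markers.
#' @param sample_id optional id carried through.
#' @return a `call_rate_result` with `rate` in percent (full precision) and
#'   `rate_reported` (half-up, one decimal).
#' @export
#' @examples
#' call_rate_counts(5376, 5379)$rate # > 99.9
call_rate_counts <- function(n_typed, n_targetable, sample_id = NA_character_) {
  n_typed <- check_count(n_typed, "n_typed")
  n_targetable <- check_count(n_targetable, "n_targetable")
  if (n_typed > n_targetable) abort("'n_typed' cannot exceed 'n_targetable'")
  new_call_rate_result(sample_id, n_typed, n_targetable)
}

#' Sex-aware call rate of a call set
#'
#' Divides the number of typed markers by the number of targetable markers:
#' the full panel for males, the panel minus Y markers for females. Unknown
#' sex is treated as male (full-panel denominator, a conservative low rate)
#' with a warning.
#'
#' @param callset a `call_set`.
#' @param panel the `snp_panel` the calls were made on.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @return a `call_rate_result`.
#' @export
call_rate <- function(callset, panel, sex = c("male", "female", "unknown")) {
  sex <- match.arg(sex)
  if (!inherits(callset, "call_set")) abort("'callset' must be a call_set")
  validate_panel(panel)
  n_y <- sum(chrom_class_of(panel) == "Y")
  n_target <- nrow(panel) - if (sex == "female") n_y else 0L
  if (sex == "unknown") {
    warning("sex unknown: using the full panel (male) denominator", call. = FALSE)
  }
  new_call_rate_result(callset$sample_id, n_typed(callset), n_target)
}

#' @export
print.call_rate_result <- function(x, ...) {
  cat(sprintf("<call_rate '%s'> %d / %d typed = %s%%\n",
              x$sample_id, x$n_typed, x$n_targetable,
              if (is.na(x$rate)) "NA" else format(x$rate_reported)))
  invisible(x)
}

#' Dynamic top-N call rate
#'
#' Selects the `n` markers with the highest total read depth for the sample
#' (ties broken lexicographically by marker id), calls them with the given
#' thresholds (diploid rule) and reports typed / `n`. The denominator stays
#' `n` even when fewer markers have reads, so sparsely covered samples are
#' penalised rather than flattered. This levels the playing field between
#' assays whose panels differ by orders of magnitude in size.
#'
#' @param reads read-count data.frame for one sample.
#' @param thresholds a [calling_thresholds()] object.
#' @param n number of top-coverage markers to call (default 5000).
#' @param sample_id optional id carried through.
#' @return a `call_rate_result` with `n_targetable = n`.
#' @export
dynamic_top_n_call_rate <- function(reads, thresholds, n = 5000,
                                    sample_id = NA_character_) {
  n <- check_count(n, "n", min = 1L)
  validate_sites(reads)
  depth <- reads$n_fwd + reads$n_rev
  ord <- order_radix(-depth, reads$marker_id)
  top <- reads[ord[seq_len(min(n, nrow(reads)))], , drop = FALSE]
  calls <- call_sites(top, thresholds, "diploid")
  new_call_rate_result(sample_id, sum(calls$call != "no_call"), n)
}

#' Per-sample sequencing run metrics
#'
#' Derives the run-level proportions plotted in assay comparisons from raw
#' read counts: proportion of human reads among all reads, proportion of
#' on-target reads among human reads, proportion of PCR duplicates among
#' on-target reads, and mean per-marker coverage. Accepts either the
#' bookkeeping of a [simulate_reads()] result or a user-supplied metrics
#' table with the count columns below.
#'
#' @param x a `sim_reads` object or data.frame with columns `sample_id`,
#'   `total_reads`, `human_reads`, `on_target_reads`, `duplicate_reads`,
#'   `mean_coverage`.
#' @return data.frame with `sample_id`, `total_reads`, `proportion_human`,
#'   `proportion_on_target`, `proportion_duplicates`, `mean_coverage`.
#' @export
summarize_run <- function(x) {
  if (inherits(x, "sim_reads")) x <- x$bookkeeping
  if (!is.data.frame(x)) abort("'x' must be a sim_reads object or a metrics data.frame")
  needed <- c("sample_id", "total_reads", "human_reads", "on_target_reads",
              "duplicate_reads", "mean_coverage")
  miss <- setdiff(needed, names(x))
  if (length(miss)) abort("metrics table is missing columns: ", paste(miss, collapse = ", "))
  data.frame(
    sample_id = x$sample_id,
    total_reads = x$total_reads,
    proportion_human = x$human_reads / x$total_reads,
    proportion_on_target = x$on_target_reads / x$human_reads,
    proportion_duplicates = x$duplicate_reads / x$on_target_reads,
    mean_coverage = x$mean_coverage,
    stringsAsFactors = FALSE
  )
}

#' Regression of called-SNP counts on sequencing parameters
#'
#' Ordinary least squares of the per-sample number of called SNPs on
#' sequencing predictors (DNA input, total/trimmed sequences, human reads,
#' mapped reads, on-target reads, duplicates, ...), with two-sided t-test
#' p-values per coefficient.
#'
#' @param metrics data.frame of numeric predictors, one row per sample.
#' @param n_called numeric vector of called-SNP counts, same length.
#' @return list with `coefficients` (data.frame `term`, `estimate`,
#'   `std_error`, `t_value`, `p_value`) and the underlying `model`.
#' @export
regress_called_snps <- function(metrics, n_called) {
  if (!is.data.frame(metrics) || !nrow(metrics)) abort("'metrics' must be a non-empty data.frame")
  if (length(n_called) != nrow(metrics)) abort("'n_called' must match the rows of 'metrics'")
  num <- vapply(metrics, is.numeric, logical(1))
  if (!all(num)) abort("non-numeric predictor columns: ",
                       paste(names(metrics)[!num], collapse = ", "))
  if (nrow(metrics) < ncol(metrics) + 2L) {
    abort("need at least ", ncol(metrics) + 2L, " samples for ", ncol(metrics), " predictors")
  }
  dat <- cbind(.n_called = n_called, metrics)
  X <- stats::model.matrix(~ ., data = metrics)
  if (qr(X)$rank < ncol(X)) {
    abort("rank-deficient design: predictors are collinear; remove redundant predictors")
  }
  fit <- stats::lm(.n_called ~ ., data = dat)
  cf <- summary(fit)$coefficients
  list(
    coefficients = data.frame(
      term = rownames(cf), estimate = cf[, 1], std_error = cf[, 2],
      t_value = cf[, 3], p_value = cf[, 4],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    model = fit
  )
}

#' One-way ANOVA with Tukey HSD across assay call rates
#'
#' Fixed-effects one-way ANOVA of call rates across assays followed by
#' Tukey's honestly-significant-difference post-hoc test (Tukey-Kramer at
#' unequal group sizes, via the studentized range distribution).
#'
#' @param groups named list (>= 2 entries) of numeric call-rate vectors, one
#'   per assay, each with >= 2 values.
#' @return list with `anova_p` (overall F-test p-value), `tukey` (data.frame
#'   `comparison`, `diff`, `lwr`, `upr`, `p_adj`) and the `aov` `fit`.
#' @export
compare_call_rates <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) abort("need at least 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) abort("'groups' must be a named list")
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    abort("every group needs >= 2 values; too small: ",
          paste(names(groups)[sizes < 2L], collapse = ", "))
  }
  dat <- data.frame(
    rate = unlist(groups, use.names = FALSE),
    assay = factor(rep(names(groups), sizes))
  )
  if (stats::var(dat$rate) == 0) abort("degenerate input: all call rates identical")
  fit <- stats::aov(rate ~ assay, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$assay
  list(
    anova_p = an[["Pr(>F)"]][1],
    tukey = data.frame(
      comparison = rownames(tk), diff = tk[, "diff"], lwr = tk[, "lwr"],
      upr = tk[, "upr"], p_adj = tk[, "p adj"],
      row.names = NULL, stringsAsFactors = FALSE
    ),
    fit = fit
  )
}
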