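# genotype category used for concordance: R (hom/hap ref), A (hom/hap alt), H (het)
allele_category <- function(call) {
  c(hom_ref = "R", hap_ref = "R", hom_alt = "A", hap_alt = "A",
    het = "H", no_call = NA_character_)[call]
}

new_concordance_result <- function(n_overlap, n_concordant, n_false_hom,
                                   n_contra_hom, y_excluded,
                                   sample_a = NA_character_, sample_b = NA_character_) {
  rate <- if (n_overlap > 0) 100 * n_concordant / n_overlap else NA_real_
  structure(
    list(sample_a = sample_a, sample_b = sample_b,
         n_overlap = n_overlap, n_concordant = n_concordant,
         rate = rate, rate_reported = round_half_up(rate, 1),
         n_false_homozygote = n_false_hom,
         n_contradictory_homozygote = n_contra_hom,
         y_excluded = y_excluded),
    class = "concordance_result"
  )
}

#' Genotype concordance between two call sets
#'
#' Overlap is the set of markers typed (call != no_call) in both call sets,
#' excluding Y markers when `exclude_y = TRUE` (Y markers, being haploid and
#' shared within paternal lineages, otherwise inflate concordance between
#' different male individuals). Discordant pairs are classified as false
#' homozygotes (het vs hom, the signature of allele drop-out/drop-in) or
#' contradictory homozygotes (opposite homozygotes). A haploid and a diploid
#' call at the same marker are concordant when the haploid allele matches the
#' dosage-equivalent homozygote (hap_ref ~ hom_ref), contradictory otherwise.
#'
#' The full-precision rate (percent) is kept in `rate`; `rate_reported` is
#' rounded half-up to one decimal, the convention used in reports.
#'
#' @param a,b `call_set`s on a shared marker namespace.
#' @param exclude_y drop Y-chromosome markers from the overlap?
#' @return a `concordance_result` with fields `n_overlap`, `n_concordant`,
#'   `rate` (percent, `NA` when the overlap is empty), `rate_reported`,
#'   `n_false_homozygote`, `n_contradictory_homozygote`, `y_excluded`.
#' @export
compare_callsets <- function(a, b, exclude_y = FALSE) {
  if (!inherits(a, "call_set") || !inherits(b, "call_set")) {
    abort("'a' and 'b' must be call_sets")
  }
  check_flag(exclude_y, "exclude_y")
  shared <- intersect(a$calls$marker_id, b$calls$marker_id)
  if (!length(shared)) abort("call sets have disjoint marker namespaces")
  ca <- a$calls[match(shared, a$calls$marker_id), ]
  cb <- b$calls[match(shared, b$calls$marker_id), ]
  keep <- rep(TRUE, length(shared))
  if (exclude_y) keep <- chrom_class(ca$chrom) != "Y"
  typed <- keep & ca$call != "no_call" & cb$call != "no_call"
  ka <- allele_category(ca$call[typed])
  kb <- allele_category(cb$call[typed])
  concordant <- ka == kb
  false_hom <- xor(ka == "H", kb == "H")
  contra <- (ka == "R" & kb == "A") | (ka == "A" & kb == "R")
  new_concordance_result(
    n_overlap = sum(typed),
    n_concordant = sum(concordant),
    n_false_hom = sum(false_hom),
    n_contra_hom = sum(contra),
    y_excluded = exclude_y,
    sample_a = a$sample_id, sample_b = b$sample_id
  )
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance> %s vs %s: %d/%d concordant (%s%%)%s; %d false hom, %d contradictory hom\n",
    x$sample_a, x$sample_b, x$n_concordant, x$n_overlap,
    if (is.na(x$rate)) "NA" else formatC(x$rate_reported, format = "f", digits = 1),
    if (x$y_excluded) " [Y excluded]" else "",
    x$n_false_homozygote, x$n_contradictory_homozygote
  ))
  invisible(x)
}

#' Pairwise concordance for a list of call sets
#'
#' @param callsets named or unnamed list of at least two `call_set`s.
#' @param exclude_y drop Y markers from every comparison?
#' @return data.frame with one row per unordered pair (`sample_a`,
#'   `sample_b`, `n_overlap`, `n_concordant`, `rate`, `rate_reported`,
#'   `n_false_homozygote`, `n_contradictory_homozygote`); symmetric by
#'   construction, diagonal omitted.
#' @export
pairwise_concordance_matrix <- function(callsets, exclude_y = FALSE) {
  if (!is.list(callsets) || length(callsets) < 2L) abort("need at least 2 call sets")
  idx <- utils::combn(length(callsets), 2L)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    r <- compare_callsets(callsets[[idx[1, k]]], callsets[[idx[2, k]]], exclude_y)
    rows[[k]] <- data.frame(
      sample_a = r$sample_a, sample_b = r$sample_b,
      n_overlap = r$n_overlap, n_concordant = r$n_concordant,
      rate = r$rate, rate_reported = r$rate_reported,
      n_false_homozygote = r$n_false_homozygote,
      n_contradictory_homozygote = r$n_contradictory_homozygote,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}

#' Genotype accuracy against a reference truth
#'
#' Compares typed calls with reference dosages (0/1/2 diploid, 0/1 haploid).
#' Typed markers absent from the reference are excluded from the denominator
#' and counted separately. A call is correct when it maps to the reference
#' dosage: hom_ref/hap_ref to 0, het to 1 (diploid) , hom_alt to 2, hap_alt
#' to 1 (haploid).
#'
#' @param calls a `call_set`.
#' @param reference named integer vector of true dosages, names = marker ids
#'   (e.g. one column of a `truth_set`'s genotype matrix).
#' @return an `accuracy_result`: `n_typed` (evaluable markers), `n_correct`,
#'   `accuracy` (percent, `NA` when nothing is evaluable),
#'   `n_not_in_reference`.
#' @export
accuracy_vs_reference <- function(calls, reference) {
  if (!inherits(calls, "call_set")) abort("'calls' must be a call_set")
  if (is.null(names(reference))) abort("'reference' must be a named dosage vector")
  typed <- calls$calls[calls$calls$call != "no_call", ]
  ref <- reference[!is.na(reference)]
  known <- typed$marker_id %in% names(ref)
  eval_calls <- typed[known, ]
  expected <- ref[eval_calls$marker_id]
  called_dosage <- c(hom_ref = 0, hap_ref = 0, het = 1, hom_alt = 2, hap_alt = 1)[eval_calls$call]
  n_correct <- sum(called_dosage == expected)
  n_eval <- nrow(eval_calls)
  structure(
    list(sample_id = calls$sample_id,
         n_typed = n_eval,
         n_correct = n_correct,
         accuracy = if (n_eval > 0) 100 * n_correct / n_eval else NA_real_,
         n_not_in_reference = sum(!known)),
    class = "accuracy_result"
  )
}

#' @export
print.accuracy_result <- function(x, ...) {
  cat(sprintf("<accuracy '%s'> %d/%d correct (%s%%), %d typed markers not in reference\n",
              x$sample_id, x$n_correct, x$n_typed,
              if (is.na(x$accuracy)) "NA" else formatC(x$accuracy, format = "f", digits = 3),
              x$n_not_in_reference))
  invisible(x)
}

#' Pooled discordance over many comparisons
#'
#' Pools discordant and overlapping genotype counts across comparisons
#' before dividing (a ratio of sums, not a mean of rates), so comparisons
#' with many overlapping markers weigh proportionally more.
#'
#' @param results list of `concordance_result`s (or the data.frame from
#'   [pairwise_concordance_matrix()]).
#' @return list with `n_overlap`, `n_discordant`, `rate` (percent discordant,
#'   `NA` when the pooled overlap is 0) and `rate_reported` (half-up, one
#'   decimal).
#' @export
aggregate_discordance <- function(results) {
  if (inherits(results, "concordance_result")) results <- list(results)
  if (is.data.frame(results)) {
    overlap <- sum(results$n_overlap)
    conc <- sum(results$n_concordant)
  } else {
    if (!length(results)) abort("'results' must contain at least one comparison")
    stopifnot(all(vapply(results, inherits, logical(1), "concordance_result")))
    overlap <- sum(vapply(results, `[[`, numeric(1), "n_overlap"))
    conc <- sum(vapply(results, `[[`, numeric(1), "n_concordant"))
  }
  disc <- overlap - conc
  rate <- if (overlap > 0) 100 * disc / overlap else NA_real_
  list(n_overlap = overlap, n_discordant = disc, rate = rate,
       rate_reported = round_half_up(rate, 1))
}
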