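#' Genotype-calling thresholds
#'
#' Threshold set for rule-based genotype calling from per-site read counts.
#' Rules are applied in a fixed order (coverage, quality, other-allele
#' fraction, strand balance, allelic balance) so that every no-call carries
#' an unambiguous reason. Depth for the balance rule counts ref + alt reads
#' only; other-allele reads are filtered by their own rule so a third allele
#' cannot silently shift the balance.
#'
#' Defaults reflect common forensic MPS practice: minimum depth 10, minimum
#' mean Phred 20, heterozygote allelic-balance band [0.30, 0.70], at most
#' 10\% minor-allele reads for a homozygote, at least 10\% of reads on the
#' minority strand (checked only at depth >= 20), at most 10\% other-allele
#' reads. Laboratories substitute their internally validated values via the
#' arguments or a `calling:` config section.
#'
#' @param min_depth minimum ref+alt read depth to attempt a call (>= 1).
#' @param min_quality minimum mean Phred quality.
#' @param het_ab_low,het_ab_high allelic-balance band for heterozygotes.
#' @param hom_ab_max maximum minor-allele fraction for a homozygous call;
#'   must satisfy `0 <= hom_ab_max < het_ab_low <= het_ab_high < 1 - hom_ab_max`.
#' @param strand_min_fraction minimum fraction of reads on the minority strand.
#' @param strand_check_min_depth depth below which the strand rule is skipped.
#' @param max_other_fraction maximum fraction of other-allele reads.
#' @return a `calling_thresholds` list.
#' @export
#' @examples
#' thr <- calling_thresholds()
#' call_genotype(list(marker_id = "m1", n_ref = 12, n_alt = 0, n_other = 0,
#'                    n_fwd = 6, n_rev = 6, mean_q = 35), thr, "diploid")
calling_thresholds <- function(min_depth = 10,
                               min_quality = 20,
                               het_ab_low = 0.30,
                               het_ab_high = 0.70,
                               hom_ab_max = 0.10,
                               strand_min_fraction = 0.10,
                               strand_check_min_depth = 20,
                               max_other_fraction = 0.10) {
  thr <- list(
    min_depth = check_count(min_depth, "min_depth", min = 1L),
    min_quality = check_number(min_quality, "min_quality", 0, Inf),
    het_ab_low = check_number(het_ab_low, "het_ab_low", 0, 1),
    het_ab_high = check_number(het_ab_high, "het_ab_high", 0, 1),
    hom_ab_max = check_number(hom_ab_max, "hom_ab_max", 0, 1),
    strand_min_fraction = check_number(strand_min_fraction, "strand_min_fraction", 0, 0.5),
    strand_check_min_depth = check_count(strand_check_min_depth, "strand_check_min_depth"),
    max_other_fraction = check_number(max_other_fraction, "max_other_fraction", 0, 1)
  )
  if (!(thr$hom_ab_max < thr$het_ab_low && thr$het_ab_low <= thr$het_ab_high &&
        thr$het_ab_high < 1 - thr$hom_ab_max)) {
    abort("thresholds must satisfy 0 <= hom_ab_max < het_ab_low <= het_ab_high < 1 - hom_ab_max")
  }
  structure(thr, class = "calling_thresholds")
}

#' @rdname calling_thresholds
#' @param profile named threshold profile. `"force_like"` and `"twist_like"`
#'   are placeholders sharing the package defaults; laboratories are expected
#'   to overwrite them with their validated per-assay values.
#' @param ... overrides passed to [calling_thresholds()].
#' @export
calling_profile <- function(profile = c("force_like", "twist_like"), ...) {
  profile <- match.arg(profile)
  thr <- calling_thresholds(...)
  attr(thr, "profile") <- profile
  thr
}

call_levels <- c("hom_ref", "het", "hom_alt", "hap_ref", "hap_alt", "no_call")
reason_levels <- c("low_depth", "low_quality", "strand_imbalance",
                   "ambiguous_balance", "excess_other", "wrong_ploidy",
                   "replicate_discordant", "none")

validate_sites <- function(sites) {
  cols <- c("n_ref", "n_alt", "n_other", "n_fwd", "n_rev", "mean_q")
  miss <- setdiff(c("marker_id", cols), names(sites))
  if (length(miss)) abort("site data missing columns: ", paste(miss, collapse = ", "))
  cnt <- c("n_ref", "n_alt", "n_other", "n_fwd", "n_rev")
  for (cc in cnt) {
    if (any(is.na(sites[[cc]]) | sites[[cc]] < 0 | sites[[cc]] != floor(sites[[cc]]))) {
      abort(sprintf("'%s' must be non-negative integer counts", cc))
    }
  }
  if (any(is.na(sites$mean_q) | sites$mean_q < 0)) abort("'mean_q' must be >= 0")
  bad <- which(sites$n_fwd + sites$n_rev != sites$n_ref + sites$n_alt + sites$n_other)
  if (length(bad)) {
    abort("strand counts do not sum to total reads at marker(s): ",
          paste(utils::head(sites$marker_id[bad], 5), collapse = ", "))
  }
  invisible(sites)
}

# vectorised rule engine; ploidy is one of "diploid", "haploid", "none" per row
call_sites <- function(sites, thresholds, ploidy) {
  validate_sites(sites)
  if (!inherits(thresholds, "calling_thresholds")) {
    abort("'thresholds' must be created by calling_thresholds()")
  }
  m <- nrow(sites)
  ploidy <- rep_len(ploidy, m)
  call <- rep("no_call", m)
  reason <- rep("none", m)

  d <- sites$n_ref + sites$n_alt
  tot <- d + sites$n_other
  strand_tot <- sites$n_fwd + sites$n_rev
  ab <- ifelse(d > 0, sites$n_alt / d, NA_real_)
  other_frac <- ifelse(tot > 0, sites$n_other / tot, 0)
  minor_strand <- ifelse(strand_tot > 0,
                         pmin(sites$n_fwd, sites$n_rev) / strand_tot, 0)

  undecided <- rep(TRUE, m)
  fail <- function(cond, why) {
    hit <- undecided & cond
    reason[hit] <<- why
    undecided[hit] <<- FALSE
  }
  fail(ploidy == "none", "wrong_ploidy")
  fail(d < thresholds$min_depth, "low_depth")
  fail(sites$mean_q < thresholds$min_quality, "low_quality")
  fail(other_frac > thresholds$max_other_fraction, "excess_other")
  fail(d >= thresholds$strand_check_min_depth &
         minor_strand < thresholds$strand_min_fraction, "strand_imbalance")

  dip <- undecided & ploidy == "diploid"
  hap <- undecided & ploidy == "haploid"
  call[dip & ab <= thresholds$hom_ab_max] <- "hom_ref"
  call[dip & ab >= 1 - thresholds$hom_ab_max] <- "hom_alt"
  call[dip & ab >= thresholds$het_ab_low & ab <= thresholds$het_ab_high] <- "het"
  call[hap & ab <= thresholds$hom_ab_max] <- "hap_ref"
  call[hap & ab >= 1 - thresholds$hom_ab_max] <- "hap_alt"
  reason[undecided & call == "no_call"] <- "ambiguous_balance"
  reason[call != "no_call"] <- "none"

  data.frame(marker_id = sites$marker_id, call = call, no_call_reason = reason,
             stringsAsFactors = FALSE)
}

#' Call a genotype at a single site
#'
#' Applies the threshold rules in fixed order: (1) ref+alt depth below
#' `min_depth` -> `low_depth`; (2) mean quality below `min_quality` ->
#' `low_quality`; (3) other-allele fraction above `max_other_fraction` ->
#' `excess_other`; (4) at depth >= `strand_check_min_depth`, minority-strand
#' fraction below `strand_min_fraction` -> `strand_imbalance`; (5) allelic
#' balance `n_alt / (n_ref + n_alt)`: at or below `hom_ab_max` -> hom_ref
#' (hap_ref when haploid), at or above `1 - hom_ab_max` -> hom_alt/hap_alt,
#' inside the het band -> het (diploid only), anything else ->
#' `ambiguous_balance`.
#'
#' @param site a list or one-row data.frame with fields `marker_id`, `n_ref`,
#'   `n_alt`, `n_other`, `n_fwd`, `n_rev`, `mean_q`.
#' @param thresholds a [calling_thresholds()] object.
#' @param ploidy `"diploid"` or `"haploid"`.
#' @return one-row data.frame with `marker_id`, `call`, `no_call_reason`.
#' @export
call_genotype <- function(site, thresholds, ploidy = c("diploid", "haploid")) {
  ploidy <- match.arg(ploidy)
  site <- as.data.frame(site, stringsAsFactors = FALSE)
  if (nrow(site) != 1L) abort("'site' must describe exactly one marker")
  call_sites(site, thresholds, ploidy)
}

#' Call all genotypes for one sample
#'
#' Applies the diploid rule at autosomes (and X in females), the haploid rule
#' at Y in males (and X in males); Y markers in female or unknown-sex samples
#' are no-calls with reason `wrong_ploidy`. Panel markers absent from the
#' read table are no-calls with reason `low_depth`. The result is independent
#' of the row order of `reads`.
#'
#' @param reads read-count data.frame for one sample (columns `marker_id`,
#'   `n_ref`, `n_alt`, `n_other`, `n_fwd`, `n_rev`, `mean_q`).
#' @param panel the `snp_panel` defining the marker space.
#' @param thresholds a [calling_thresholds()] object.
#' @param sex `"male"`, `"female"` or `"unknown"`.
#' @param sample_id sample identifier stored in the call set.
#' @return a `call_set`: list with `sample_id`, `calls` (data.frame
#'   `marker_id`, `chrom`, `call`, `no_call_reason`, one row per panel
#'   marker), `thresholds`, `panel_name`.
#' @export
call_sample <- function(reads, panel, thresholds,
                        sex = c("male", "female", "unknown"),
                        sample_id = "sample") {
  sex <- match.arg(sex)
  validate_panel(panel)
  unknown <- setdiff(reads$marker_id, panel$marker_id)
  if (length(unknown)) {
    abort("read table contains marker ids not in the panel: ",
          paste(utils::head(unknown, 10), collapse = ", "))
  }
  if (anyDuplicated(reads$marker_id)) {
    abort("read table has duplicated marker ids for one sample")
  }
  idx <- match(panel$marker_id, reads$marker_id)
  aligned <- data.frame(
    marker_id = panel$marker_id,
    n_ref = ifelse(is.na(idx), 0L, reads$n_ref[idx]),
    n_alt = ifelse(is.na(idx), 0L, reads$n_alt[idx]),
    n_other = ifelse(is.na(idx), 0L, reads$n_other[idx]),
    n_fwd = ifelse(is.na(idx), 0L, reads$n_fwd[idx]),
    n_rev = ifelse(is.na(idx), 0L, reads$n_rev[idx]),
    mean_q = ifelse(is.na(idx), 0, reads$mean_q[idx]),
    stringsAsFactors = FALSE
  )
  cls <- chrom_class_of(panel)
  ploidy <- rep("diploid", nrow(panel))
  ploidy[cls == "Y"] <- if (sex == "male") "haploid" else "none"
  ploidy[cls == "X" & sex == "male"] <- "haploid"
  calls <- call_sites(aligned, thresholds, ploidy)
  calls <- data.frame(marker_id = calls$marker_id, chrom = panel$chrom,
                      call = calls$call, no_call_reason = calls$no_call_reason,
                      stringsAsFactors = FALSE)
  new_call_set(sample_id, calls, thresholds, attr(panel, "name") %||% "panel")
}

new_call_set <- function(sample_id, calls, thresholds, panel_name) {
  stopifnot(all(calls$call %in% call_levels),
            all(calls$no_call_reason %in% reason_levels),
            !anyDuplicated(calls$marker_id))
  structure(
    list(sample_id = sample_id, calls = calls, thresholds = thresholds,
         panel_name = panel_name),
    class = "call_set"
  )
}

#' Number of typed markers in a call set
#' @param callset a `call_set`.
#' @return integer count of markers with a call other than `no_call`.
#' @export
n_typed <- function(callset) {
  if (!inherits(callset, "call_set")) abort("'callset' must be a call_set")
  sum(callset$calls$call != "no_call")
}

#' Consensus calls across two replicates of the same sample
#'
#' A marker is typed in the consensus if and only if it is typed with an
#' identical call in both replicates. Markers typed discordantly become
#' no-calls with reason `replicate_discordant`; markers untyped in either
#' input inherit that input's no-call reason. The consensus typed set is by
#' construction a subset of each input's typed set, trading overlap for
#' reliability.
#'
#' @param a,b `call_set`s of two replicates on the same panel.
#' @return the consensus `call_set`.
#' @export
consensus_replicates <- function(a, b) {
  if (!inherits(a, "call_set") || !inherits(b, "call_set")) {
    abort("'a' and 'b' must be call_sets")
  }
  if (!identical(a$panel_name, b$panel_name) ||
      !identical(sort(a$calls$marker_id), sort(b$calls$marker_id))) {
    abort("replicate call sets are not on the same panel")
  }
  bb <- b$calls[match(a$calls$marker_id, b$calls$marker_id), ]
  aa <- a$calls
  typed_a <- aa$call != "no_call"
  typed_b <- bb$call != "no_call"
  agree <- typed_a & typed_b & aa$call == bb$call
  call <- ifelse(agree, aa$call, "no_call")
  reason <- ifelse(agree, "none",
            ifelse(typed_a & typed_b, "replicate_discordant",
            ifelse(!typed_a, aa$no_call_reason, bb$no_call_reason)))
  calls <- data.frame(marker_id = aa$marker_id, chrom = aa$chrom,
                      call = call, no_call_reason = reason,
                      stringsAsFactors = FALSE)
  out <- new_call_set(paste0(a$sample_id, "+", b$sample_id), calls,
                      a$thresholds, a$panel_name)
  attr(out, "consensus_of") <- c(a$sample_id, b$sample_id)
  out
}

#' @export
print.call_set <- function(x, ...) {
  tab <- table(factor(x$calls$call, levels = call_levels))
  cat(sprintf("<call_set '%s'> %d markers, %d typed (%.1f%%)\n",
              x$sample_id, nrow(x$calls), n_typed(x),
              100 * n_typed(x) / nrow(x$calls)))
  print(tab)
  invisible(x)
}
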