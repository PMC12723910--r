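#' Configuration of the degraded-sample read-count simulator
#'
#' Captures the generative model for per-SNP read counts observed after the
#' upstream read-processing stages (trimming, human-read filtering, mapping,
#' duplicate removal) of a capture or shotgun workflow. Per-marker depth is
#' negative-binomial with mean `mean_depth * t_j`, where `t_j` is a lognormal
#' per-marker capture efficiency with mean 1 shared by all samples (this is
#' what makes some markers systematically deep across samples, as in capture
#' data, while keeping the marginal expected depth equal to `mean_depth`). Each read is independently: an "other"-allele misread with
#' probability `error_rate/3`; otherwise a contaminant read with probability
#' `contamination` (alleles drawn from one independent HWE individual,
#' resimulated per sample), else an endogenous read whose alt-allele
#' probability follows the binomial error model used by the match engine,
#' with an extra symmetric ref<->alt flip `damage_rate` at C/T- and
#' G/A-typed markers standing in for terminal deamination.
#'
#' `nonhuman_fraction` and `duplicate_fraction` do not change the count
#' tables; they drive the run-metrics bookkeeping (total, human, on-target
#' and duplicate read counts) consumed by [summarize_run()].
#'
#' @param mean_depth mean reads per SNP (> 0); degraded shotgun data sit
#'   around 0.3x, capture panels tens of reads, controls 100x or more.
#' @param depth_dispersion negative-binomial size parameter (> 0); the
#'   Poisson limit is `Inf`.
#' @param site_efficiency_sd lognormal sd of the per-marker efficiency (>= 0).
#' @param error_rate per-read misread probability in [0, 0.5).
#' @param damage_rate extra flip probability at damage-typed markers, [0, 0.5).
#' @param contamination fraction of reads from the contaminant, [0, 1).
#' @param mean_quality,quality_sd Phred-scale mean site quality and its sd;
#'   site qualities are normal, truncated at 2.
#' @param nonhuman_fraction fraction of all sequenced reads that are
#'   non-endogenous, [0, 1) (bookkeeping only).
#' @param duplicate_fraction fraction of mapped reads that are PCR
#'   duplicates, [0, 1) (bookkeeping only).
#' @param seed integer seed; identical config implies identical output.
#' @return a `simulation_config` list.
#' @seealso [sim_preset()] for the named presets.
#' @export
simulation_config <- function(mean_depth = 0.3,
                              depth_dispersion = 1,
                              site_efficiency_sd = 0.3,
                              error_rate = 0.01,
                              damage_rate = 0,
                              contamination = 0,
                              mean_quality = 35,
                              quality_sd = 3,
                              nonhuman_fraction = 0,
                              duplicate_fraction = 0,
                              seed = 1) {
  cfg <- list(
    mean_depth = check_number(mean_depth, "mean_depth", 0, Inf, open_min = TRUE),
    depth_dispersion = check_number(depth_dispersion, "depth_dispersion", 0, Inf, open_min = TRUE),
    site_efficiency_sd = check_number(site_efficiency_sd, "site_efficiency_sd", 0, Inf),
    error_rate = check_number(error_rate, "error_rate", 0, 0.5, open_max = TRUE),
    damage_rate = check_number(damage_rate, "damage_rate", 0, 0.5, open_max = TRUE),
    contamination = check_number(contamination, "contamination", 0, 1, open_max = TRUE),
    mean_quality = check_number(mean_quality, "mean_quality", 0, Inf),
    quality_sd = check_number(quality_sd, "quality_sd", 0, Inf),
    nonhuman_fraction = check_number(nonhuman_fraction, "nonhuman_fraction", 0, 1, open_max = TRUE),
    duplicate_fraction = check_number(duplicate_fraction, "duplicate_fraction", 0, 1, open_max = TRUE),
    seed = check_count(seed, "seed")
  )
  structure(cfg, class = "simulation_config")
}

#' Named simulator presets
#'
#' Three depth regimes bracketing what degraded-sample SNP workflows see:
#' `"wgs_like"` (0.3x shotgun of a poorly preserved skeletal sample, almost
#' all reads non-endogenous), `"capture_like"` (~30x on-target with strong
#' per-marker efficiency spread and heavy duplication, as in hybridization
#' capture) and `"control_like"` (~100x clean reference material).
#'
#' @param name one of `"wgs_like"`, `"capture_like"`, `"control_like"`.
#' @param ... overrides passed on to [simulation_config()].
#' @return a `simulation_config`.
#' @export
#' @examples
#' sim_preset("wgs_like", seed = 7)$mean_depth
sim_preset <- function(name = c("wgs_like", "capture_like", "control_like"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    wgs_like = list(mean_depth = 0.3, site_efficiency_sd = 0.3,
                    nonhuman_fraction = 0.95, duplicate_fraction = 0.1),
    capture_like = list(mean_depth = 30, site_efficiency_sd = 0.8,
                        nonhuman_fraction = 0.5, duplicate_fraction = 0.3),
    control_like = list(mean_depth = 100, site_efficiency_sd = 0.3,
                        nonhuman_fraction = 0.01, duplicate_fraction = 0.1)
  )
  over <- list(...)
  base[names(over)] <- over
  do.call(simulation_config, base)
}

# alt-read probability for the three diploid dosages / two haploid dosages
alt_prob_of_dosage <- function(g, eps, haploid) {
  q <- ifelse(haploid,
    ifelse(g >= 1L, 1 - eps, eps),
    c(eps, 0.5, 1 - eps)[pmin(g, 2L) + 1L]
  )
  q
}

#' Simulate per-sample per-SNP read-count tables
#'
#' Draws, for every sample in the truth set, a read-count table with one row
#' per panel marker: `marker_id`, `n_ref`, `n_alt`, `n_other`, `n_fwd`,
#' `n_rev`, `mean_q`. Strand counts split total depth Binomial(depth, 0.5),
#' so `n_ref + n_alt + n_other = n_fwd + n_rev` holds at every site. Female
#' samples receive zero depth at Y markers. See [simulation_config()] for
#' the generative model.
#'
#' @param truth a `truth_set` from [simulate_individuals()].
#' @param panel the `snp_panel` the truth set was drawn on.
#' @param cfg a `simulation_config`.
#' @return a `sim_reads` list: `reads` (named list of per-sample
#'   data.frames), `bookkeeping` (per-sample read-accounting data.frame),
#'   `panel_name`, `config`.
#' @export
simulate_reads <- function(truth, panel, cfg) {
  validate_truth(truth)
  validate_panel(panel)
  if (!inherits(cfg, "simulation_config")) abort("'cfg' must be a simulation_config")
  if (!identical(rownames(truth$genotypes), panel$marker_id)) {
    abort("truth set and panel marker spaces differ")
  }
  set.seed(cfg$seed)
  m <- nrow(panel)
  cls <- chrom_class_of(panel)
  eps <- cfg$error_rate
  delta <- cfg$damage_rate
  pair <- paste(pmin(panel$ref, panel$alt), pmax(panel$ref, panel$alt))
  damage_typed <- pair %in% c("C T", "A G")
  # mean-1 lognormal so E[depth] = mean_depth regardless of the efficiency sd
  t_j <- if (cfg$site_efficiency_sd > 0) {
    stats::rlnorm(m, meanlog = -cfg$site_efficiency_sd^2 / 2,
                  sdlog = cfg$site_efficiency_sd)
  } else {
    rep(1, m)
  }
  mu <- cfg$mean_depth * t_j
  sexes <- truth$samples$sex
  ids <- truth$samples$sample_id
  reads <- vector("list", length(ids))
  names(reads) <- ids
  book <- data.frame(
    sample_id = ids, total_reads = NA_real_, human_reads = NA_real_,
    mapped_reads = NA_real_, on_target_reads = NA_real_,
    duplicate_reads = NA_real_, mean_coverage = NA_real_,
    stringsAsFactors = FALSE
  )
  for (s in seq_along(ids)) {
    depth <- if (is.finite(cfg$depth_dispersion)) {
      stats::rnbinom(m, size = cfg$depth_dispersion, mu = mu)
    } else {
      stats::rpois(m, mu)
    }
    sex <- sexes[s]
    haploid <- cls == "Y" | (cls == "X" & sex == "male")
    g <- truth$genotypes[, s]
    no_template <- is.na(g) # female Y: no chromosome to sequence
    depth[no_template] <- 0L

    q_true <- alt_prob_of_dosage(g, eps, haploid)
    # contaminant: one independent HWE (male-ploidy) individual per sample
    if (cfg$contamination > 0) {
      gc <- rep(NA_integer_, m)
      gc[!haploid] <- stats::rbinom(sum(!haploid), 2L, panel$alt_freq[!haploid])
      gc[haploid] <- stats::rbinom(sum(haploid), 1L, panel$alt_freq[haploid])
      q_cont <- alt_prob_of_dosage(gc, eps, haploid)
    } else {
      q_cont <- q_true
    }
    if (delta > 0) {
      q_true <- ifelse(damage_typed, q_true * (1 - delta) + (1 - q_true) * delta, q_true)
      q_cont <- ifelse(damage_typed, q_cont * (1 - delta) + (1 - q_cont) * delta, q_cont)
    }
    q_true[no_template] <- 0
    q_cont[no_template] <- 0

    n_other <- stats::rbinom(m, depth, eps / 3)
    n_inf <- depth - n_other
    n_cont <- stats::rbinom(m, n_inf, cfg$contamination)
    n_end <- n_inf - n_cont
    n_alt <- stats::rbinom(m, n_end, q_true) + stats::rbinom(m, n_cont, q_cont)
    n_ref <- n_inf - n_alt
    n_fwd <- stats::rbinom(m, depth, 0.5)
    n_rev <- depth - n_fwd
    mean_q <- round(pmax(stats::rnorm(m, cfg$mean_quality, cfg$quality_sd), 2), 2)
    mean_q[depth == 0L] <- 0

    reads[[s]] <- data.frame(
      marker_id = panel$marker_id,
      n_ref = n_ref, n_alt = n_alt, n_other = n_other,
      n_fwd = n_fwd, n_rev = n_rev, mean_q = mean_q,
      stringsAsFactors = FALSE
    )
    dedup <- sum(depth)
    mapped <- ceiling(dedup / (1 - cfg$duplicate_fraction))
    human <- mapped # simulated reads are all human and on-target
    total <- ceiling(human / (1 - cfg$nonhuman_fraction))
    book[s, -1] <- c(total, human, mapped, mapped, mapped - dedup, dedup / m)
  }
  structure(
    list(reads = reads, bookkeeping = book,
         panel_name = attr(panel, "name") %||% "panel", config = cfg),
    class = "sim_reads"
  )
}

#' @export
print.sim_reads <- function(x, ...) {
  cat(sprintf(
    "<sim_reads> %d samples x %d markers (mean depth %.3g, panel '%s')\n",
    length(x$reads), nrow(x$reads[[1]]), x$config$mean_depth, x$panel_name
  ))
  invisible(x)
}
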