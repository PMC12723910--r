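#' Run the full simulate-call-match-evaluate pipeline
#'
#' Executes the five analysis stages on a synthetic study defined by the
#' config: (1) simulate a panel, individuals (plus replicates of the first
#' sample) and per-sample read counts; (2) call genotypes per sample; (3)
#' select markers and compute all pairwise direct-match likelihood ratios;
#' (4) compute all pairwise genotype concordances; (5) compute per-sample
#' call rates and run metrics. All tables are written as TSV into `out_dir`
#' together with the effective config and a manifest (seed, config hash,
#' package version, per-stage record counts). Reruns with the same config
#' produce byte-identical tables and the same config hash.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param quiet suppress per-stage messages?
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) abort("'config' must be a pipeline_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  counts <- list()
  des <- config$design

  sim <- stage("simulate", {
    panel <- build_panel(des$n_autosomal, des$n_y, seed = config$seed,
                         name = "pipeline_panel")
    truth <- simulate_individuals(panel, des$n_samples, des$sex_ratio,
                                  seed = config$seed + 1L)
    if (des$n_replicates > 0) {
      truth <- add_replicates(truth, truth$samples$sample_id[1], des$n_replicates)
    }
    cfg <- config$simulate
    cfg$seed <- config$seed + 2L
    reads <- simulate_reads(truth, panel, cfg)
    write_panel(panel, file.path(out_dir, "panel.tsv"))
    write_truth(truth, file.path(out_dir, "truth.tsv"))
    write_tsv_file(pair_labels(truth), file.path(out_dir, "pairs.tsv"))
    write_reads(reads$reads, file.path(out_dir, "reads.tsv"))
    list(panel = panel, truth = truth, reads = reads)
  })
  counts$samples <- nrow(sim$truth$samples)
  counts$markers <- nrow(sim$panel)
  say("simulate: %d samples x %d markers", counts$samples, counts$markers)

  callsets <- stage("call", {
    cs <- lapply(seq_len(nrow(sim$truth$samples)), function(i) {
      call_sample(sim$reads$reads[[i]], sim$panel, config$calling,
                  sex = sim$truth$samples$sex[i],
                  sample_id = sim$truth$samples$sample_id[i])
    })
    names(cs) <- sim$truth$samples$sample_id
    write_calls(cs, file.path(out_dir, "calls.tsv"))
    cs
  })
  counts$typed_total <- sum(vapply(callsets, n_typed, integer(1)))
  say("call: %d genotypes typed in total", counts$typed_total)

  matches <- stage("match", {
    markers <- select_snps(sim$reads$reads, sim$panel, des$n_select)
    mm <- pairwise_match_matrix(sim$reads$reads, markers,
                                config$match$error, config$match$rules)
    write_tsv_file(mm, file.path(out_dir, "matches.tsv"))
    mm
  })
  counts$pairs <- nrow(matches)
  say("match: %d pairwise comparisons", counts$pairs)

  conc <- stage("concordance", {
    cm <- pairwise_concordance_matrix(callsets, exclude_y = FALSE)
    write_tsv_file(cm, file.path(out_dir, "concordance.tsv"))
    cm
  })
  say("concordance: pooled discordance %.2f%%",
      aggregate_discordance(conc)$rate %||% NA)

  metrics <- stage("metrics", {
    rates <- do.call(rbind, lapply(seq_along(callsets), function(i) {
      r <- call_rate(callsets[[i]], sim$panel, sex = sim$truth$samples$sex[i])
      data.frame(sample_id = r$sample_id, n_typed = r$n_typed,
                 n_targetable = r$n_targetable, call_rate = r$rate,
                 stringsAsFactors = FALSE)
    }))
    run <- summarize_run(sim$reads)
    merged <- merge(rates, run, by = "sample_id", sort = TRUE)
    write_tsv_file(merged, file.path(out_dir, "metrics.tsv"))
    merged
  })
  say("metrics: %d samples summarised", nrow(metrics))

  config_path <- file.path(out_dir, "config.json")
  write_config(config, config_path)
  manifest <- list(
    package = "forensnp",
    version = as.character(utils::packageVersion("forensnp")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(config_path)),
    counts = counts,
    outputs = c("panel.tsv", "truth.tsv", "pairs.tsv", "reads.tsv",
                "calls.tsv", "matches.tsv", "concordance.tsv", "metrics.tsv",
                "config.json")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
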