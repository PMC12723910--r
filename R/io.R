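# shared TSV reading with header validation; returns df plus source line numbers
read_tsv_file <- function(path, required, optional = character(0)) {
  if (!file.exists(path)) abort("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s): %s", path, paste(miss, collapse = ", ")))
  }
  extra <- setdiff(names(df), c(required, optional))
  if (length(extra)) {
    abort(sprintf("%s: unexpected column(s): %s", path, paste(extra, collapse = ", ")))
  }
  df
}

write_tsv_file <- function(df, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

# data line number in the file (header is line 1)
line_no <- function(i) i + 1L

#' Read and write panel TSV files
#'
#' Panel files are tab-separated with header
#' `marker_id, chrom, pos, ref, alt, alt_freq`. Reading validates uniqueness
#' of marker ids, allele sanity and frequency bounds, reporting offending
#' line numbers; writing emits a deterministic column order so a write/read
#' round trip reproduces the panel exactly.
#'
#' @param path file path.
#' @param panel a `snp_panel`.
#' @param name panel name (defaults to the file name).
#' @return `read_panel()` returns a `snp_panel`; `write_panel()` its path,
#'   invisibly.
#' @export
read_panel <- function(path, name = NULL) {
  df <- read_tsv_file(path, c("marker_id", "chrom", "pos", "ref", "alt", "alt_freq"))
  df <- df[, c("marker_id", "chrom", "pos", "ref", "alt", "alt_freq")]
  df$marker_id <- as.character(df$marker_id)
  df$chrom <- as.character(df$chrom)
  dup <- which(duplicated(df$marker_id))
  if (length(dup)) {
    abort(sprintf("%s: duplicate marker_id '%s' at line %d",
                  path, df$marker_id[dup[1]], line_no(dup[1])))
  }
  freq <- suppressWarnings(as.numeric(df$alt_freq))
  bad <- which(is.na(freq) & !is.na(df$alt_freq) | freq < 0 | freq > 1)
  if (length(bad)) {
    abort(sprintf("%s: malformed alt_freq '%s' at line %d",
                  path, df$alt_freq[bad[1]], line_no(bad[1])))
  }
  df$alt_freq <- freq
  bad <- which(!grepl("^[ACGT]$", df$ref) | !grepl("^[ACGT]$", df$alt) | df$ref == df$alt)
  if (length(bad)) {
    abort(sprintf("%s: invalid ref/alt alleles at line %d", path, line_no(bad[1])))
  }
  bad <- which(is.na(df$pos) | df$pos < 1 | df$pos != floor(df$pos))
  if (length(bad)) {
    abort(sprintf("%s: invalid position at line %d", path, line_no(bad[1])))
  }
  df$pos <- as.integer(df$pos)
  new_snp_panel(df, name %||% sub("\\.[^.]*$", "", basename(path)))
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  write_tsv_file(as.data.frame(panel)[, c("marker_id", "chrom", "pos",
                                          "ref", "alt", "alt_freq")], path)
}

#' Read and write read-count TSV files
#'
#' Read-count tables carry `marker_id, n_ref, n_alt, n_other, n_fwd, n_rev,
#' mean_q` plus an optional leading `sample_id` column (long format holding
#' several samples). The strand-sum invariant
#' `n_fwd + n_rev == n_ref + n_alt + n_other` is enforced at read time with
#' the offending line number.
#'
#' @param path file path.
#' @param reads a single read-count data.frame, or a named list of them
#'   (written in long format with a `sample_id` column).
#' @return `read_reads()` returns the data.frame (with `sample_id` when
#'   present in the file); `split_reads()` splits a long table into the named
#'   list form used by the match engine.
#' @export
read_reads <- function(path) {
  cols <- c("marker_id", "n_ref", "n_alt", "n_other", "n_fwd", "n_rev", "mean_q")
  df <- read_tsv_file(path, cols, optional = "sample_id")
  df$marker_id <- as.character(df$marker_id)
  for (cc in c("n_ref", "n_alt", "n_other", "n_fwd", "n_rev")) {
    bad <- which(is.na(df[[cc]]) | df[[cc]] < 0 | df[[cc]] != floor(df[[cc]]))
    if (length(bad)) {
      abort(sprintf("%s: invalid %s at line %d", path, cc, line_no(bad[1])))
    }
    df[[cc]] <- as.integer(df[[cc]])
  }
  bad <- which(df$n_fwd + df$n_rev != df$n_ref + df$n_alt + df$n_other)
  if (length(bad)) {
    abort(sprintf("%s: strand counts do not sum to total reads at line %d",
                  path, line_no(bad[1])))
  }
  if ("sample_id" %in% names(df)) {
    df <- df[, c("sample_id", cols)]
    df$sample_id <- as.character(df$sample_id)
  }
  df
}

#' @rdname read_reads
#' @export
write_reads <- function(reads, path) {
  cols <- c("marker_id", "n_ref", "n_alt", "n_other", "n_fwd", "n_rev", "mean_q")
  if (is.data.frame(reads)) {
    keep <- intersect(c("sample_id", cols), names(reads))
    write_tsv_file(reads[, keep], path)
  } else {
    if (is.null(names(reads))) abort("'reads' list must be named by sample")
    long <- do.call(rbind, lapply(names(reads), function(id) {
      cbind(sample_id = id, reads[[id]][, cols])
    }))
    write_tsv_file(long, path)
  }
}

#' @rdname read_reads
#' @param long a long-format read table with a `sample_id` column.
#' @export
split_reads <- function(long) {
  if (!"sample_id" %in% names(long)) abort("'long' must have a sample_id column")
  out <- split(long[, setdiff(names(long), "sample_id")], long$sample_id)
  lapply(out, function(df) { rownames(df) <- NULL; df })
}

#' Read and write genotype-call TSV files
#'
#' Call tables carry `sample_id, marker_id, chrom, call, no_call_reason`.
#' Reading validates the call and reason vocabularies and their consistency
#' (`no_call_reason == "none"` iff the marker is typed).
#'
#' @param path file path.
#' @param callsets a `call_set` or list of them.
#' @return `read_calls()` returns a named list of `call_set`s.
#' @export
read_calls <- function(path) {
  df <- read_tsv_file(path, c("sample_id", "marker_id", "chrom", "call", "no_call_reason"))
  bad <- which(!df$call %in% call_levels)
  if (length(bad)) {
    abort(sprintf("%s: unknown call '%s' at line %d", path, df$call[bad[1]], line_no(bad[1])))
  }
  bad <- which(!df$no_call_reason %in% reason_levels)
  if (length(bad)) {
    abort(sprintf("%s: unknown no_call_reason '%s' at line %d",
                  path, df$no_call_reason[bad[1]], line_no(bad[1])))
  }
  bad <- which((df$no_call_reason == "none") != (df$call != "no_call"))
  if (length(bad)) {
    abort(sprintf("%s: inconsistent call/no_call_reason at line %d", path, line_no(bad[1])))
  }
  by_sample <- split(df, df$sample_id)
  out <- lapply(names(by_sample), function(id) {
    calls <- by_sample[[id]][, c("marker_id", "chrom", "call", "no_call_reason")]
    rownames(calls) <- NULL
    new_call_set(id, calls, NULL, sub("\\.[^.]*$", "", basename(path)))
  })
  stats::setNames(out, names(by_sample))
}

#' @rdname read_calls
#' @export
write_calls <- function(callsets, path) {
  if (inherits(callsets, "call_set")) callsets <- list(callsets)
  long <- do.call(rbind, lapply(callsets, function(cs) {
    cbind(sample_id = cs$sample_id,
          cs$calls[, c("marker_id", "chrom", "call", "no_call_reason")])
  }))
  write_tsv_file(long, path)
}

#' Read and write truth TSV files
#'
#' Truth tables are long format `sample_id, marker_id, dosage`; pair-label
#' tables are `sample_a, sample_b, relation`.
#'
#' @param truth a `truth_set`.
#' @param path file path.
#' @return `read_truth()` returns a data.frame; `truth_to_long()` flattens a
#'   `truth_set` for writing.
#' @export
truth_to_long <- function(truth) {
  validate_truth(truth)
  g <- truth$genotypes
  long <- data.frame(
    sample_id = rep(colnames(g), each = nrow(g)),
    marker_id = rep(rownames(g), times = ncol(g)),
    dosage = as.vector(g),
    stringsAsFactors = FALSE
  )
  long[!is.na(long$dosage), ]
}

#' @rdname truth_to_long
#' @export
write_truth <- function(truth, path) write_tsv_file(truth_to_long(truth), path)

#' @rdname truth_to_long
#' @export
read_truth <- function(path) {
  df <- read_tsv_file(path, c("sample_id", "marker_id", "dosage"))
  bad <- which(is.na(df$dosage) | !df$dosage %in% 0:2)
  if (length(bad)) {
    abort(sprintf("%s: invalid dosage at line %d", path, line_no(bad[1])))
  }
  df$dosage <- as.integer(df$dosage)
  df
}

#' Pipeline configuration
#'
#' Assembles the full configuration of a pipeline run: calling thresholds,
#' match error model and classification rules, simulator settings and the
#' simulated study design. [read_config()] loads the same structure from a
#' strict JSON file (JSON is a YAML-compatible mapping); unknown keys are
#' rejected rather than ignored.
#'
#' @param calling a [calling_thresholds()] object or argument list.
#' @param match list with `error` ([error_model()] or argument list) and
#'   `rules` ([match_rules()] or argument list).
#' @param simulate a [simulation_config()] or argument list.
#' @param design list controlling the simulated study: `n_autosomal`, `n_y`,
#'   `n_samples`, `sex_ratio`, `n_replicates` (replicates of the first
#'   sample), `n_select` (markers entering the LR stage).
#' @param seed integer master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(calling = list(), match = list(), simulate = list(),
                            design = list(), seed = 1) {
  build <- function(x, cls, ctor) {
    if (inherits(x, cls)) return(x)
    if (!is.list(x)) abort("config section must be a list")
    tryCatch(do.call(ctor, x), error = function(e) {
      abort("invalid config section: ", conditionMessage(e))
    })
  }
  if (!is.list(match)) abort("'match' must be a list")
  bad <- setdiff(names(match), c("error", "rules"))
  if (length(bad)) abort("unknown keys in match config: ", paste(bad, collapse = ", "))
  design_defaults <- list(n_autosomal = 2000, n_y = 100, n_samples = 6,
                          sex_ratio = 0.5, n_replicates = 1, n_select = 1000)
  bad <- setdiff(names(design), names(design_defaults))
  if (length(bad)) abort("unknown keys in design config: ", paste(bad, collapse = ", "))
  design_defaults[names(design)] <- design
  structure(
    list(
      calling = build(calling, "calling_thresholds", calling_thresholds),
      match = list(
        error = build(match$error %||% list(), "error_model", error_model),
        rules = build(match$rules %||% list(), "match_rules", match_rules)
      ),
      simulate = build(simulate, "simulation_config", simulation_config),
      design = design_defaults,
      seed = check_count(seed, "seed")
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param path path to a JSON config file with (optional) top-level sections
#'   `calling`, `match`, `simulate`, `design` and `seed`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(raw)) abort("config must be a JSON mapping")
  known <- c("calling", "match", "simulate", "design", "seed")
  bad <- setdiff(names(raw), known)
  if (length(bad)) abort("unknown config section(s): ", paste(bad, collapse = ", "))
  pipeline_config(
    calling = raw$calling %||% list(),
    match = raw$match %||% list(),
    simulate = raw$simulate %||% list(),
    design = raw$design %||% list(),
    seed = raw$seed %||% 1
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) abort("'config' must be a pipeline_config")
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  out <- list(
    calling = unclass(config$calling),
    match = list(error = unclass(config$match$error)[c("base_error", "sample_error_factor", "freq_floor")],
                 rules = unclass(config$match$rules)),
    simulate = unclass(config$simulate),
    design = config$design,
    seed = config$seed
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
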