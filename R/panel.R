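#' Allele-frequency models for synthetic panels
#'
#' A frequency model describes the population alternate-allele frequency
#' distribution from which panel markers are drawn. Draws are clamped to
#' `[1e-4, 1 - 1e-4]` so no marker is exactly monomorphic.
#'
#' @param min,max bounds of the uniform model (both in (0, 1), `min < max`).
#' @param shape1,shape2 positive shape parameters of the beta model.
#' @return an object of class `freq_model`.
#' @export
#' @examples
#' freq_uniform(0.05, 0.95)
#' freq_beta(2, 2)
freq_uniform <- function(min = 0.05, max = 0.95) {
  check_number(min, "min", 0, 1, open_min = TRUE, open_max = TRUE)
  check_number(max, "max", 0, 1, open_min = TRUE, open_max = TRUE)
  if (min >= max) abort("'min' must be smaller than 'max'")
  structure(list(kind = "uniform", min = min, max = max), class = "freq_model")
}

#' @rdname freq_uniform
#' @export
freq_beta <- function(shape1 = 2, shape2 = 2) {
  check_number(shape1, "shape1", 0, Inf, open_min = TRUE)
  check_number(shape2, "shape2", 0, Inf, open_min = TRUE)
  structure(list(kind = "beta", shape1 = shape1, shape2 = shape2),
            class = "freq_model")
}

draw_freqs <- function(model, n) {
  if (!inherits(model, "freq_model")) abort("'freq_model' must be created by freq_uniform() or freq_beta()")
  x <- switch(model$kind,
    uniform = stats::runif(n, model$min, model$max),
    beta = stats::rbeta(n, model$shape1, model$shape2),
    abort(sprintf("unknown frequency model kind '%s'", model$kind))
  )
  pmin(pmax(x, 1e-4), 1 - 1e-4)
}

#' Build a synthetic biallelic SNP panel
#'
#' Generates a panel of autosomal and Y-chromosome biallelic SNP markers with
#' population alternate-allele frequencies drawn i.i.d. from a frequency
#' model. Autosomal markers are spread round-robin over chr1-chr22; ref/alt
#' alleles are drawn uniformly over ordered nucleotide pairs, so roughly a
#' third of markers are C/T- or G/A-typed and therefore exposed to the
#' deamination-like damage term of the read simulator.
#'
#' @param n_autosomal,n_y number of autosomal and Y markers (total >= 1).
#' @param freq_model a [freq_uniform()] or [freq_beta()] model.
#' @param seed integer seed; identical arguments give identical panels.
#' @param name panel name.
#' @return a `snp_panel`: a data.frame with columns `marker_id`, `chrom`,
#'   `pos`, `ref`, `alt`, `alt_freq` and a `name` attribute.
#' @export
#' @examples
#' p <- build_panel(100, 10, freq_uniform(0.05, 0.95), seed = 1)
#' table(chrom_class_of(p))
build_panel <- function(n_autosomal, n_y = 0, freq_model = freq_uniform(),
                        seed = 1, name = "synthetic_panel") {
  n_autosomal <- check_count(n_autosomal, "n_autosomal")
  n_y <- check_count(n_y, "n_y")
  seed <- check_count(seed, "seed")
  if (n_autosomal + n_y < 1L) abort("panel must contain at least one marker")
  set.seed(seed)
  m <- n_autosomal + n_y
  chrom <- c(
    if (n_autosomal > 0) paste0("chr", rep_len(1:22, n_autosomal)),
    rep("chrY", n_y)
  )
  pos <- integer(m)
  for (cc in unique(chrom)) {
    idx <- which(chrom == cc)
    pos[idx] <- seq_along(idx) * 1000L
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  panel <- data.frame(
    marker_id = sprintf("snp%07d", seq_len(m)),
    chrom = chrom,
    pos = pos,
    ref = ref,
    alt = unname(alt),
    alt_freq = draw_freqs(freq_model, m),
    stringsAsFactors = FALSE
  )
  new_snp_panel(panel, name)
}

new_snp_panel <- function(df, name) {
  rownames(df) <- NULL
  structure(df, class = c("snp_panel", "data.frame"), name = name)
}

#' Chromosome class of each panel marker
#'
#' @param panel a `snp_panel`.
#' @return character vector with values `"autosome"`, `"X"` or `"Y"`.
#' @export
chrom_class_of <- function(panel) chrom_class(panel$chrom)

validate_panel <- function(panel) {
  if (!is.data.frame(panel)) abort("'panel' must be a snp_panel data.frame")
  needed <- c("marker_id", "chrom", "pos", "ref", "alt", "alt_freq")
  miss <- setdiff(needed, names(panel))
  if (length(miss)) abort("panel is missing columns: ", paste(miss, collapse = ", "))
  dup <- panel$marker_id[duplicated(panel$marker_id)]
  if (length(dup)) abort("duplicate marker_id in panel: ", paste(unique(dup), collapse = ", "))
  if (any(panel$ref == panel$alt)) abort("panel has markers with ref == alt")
  bad <- !is.na(panel$alt_freq) & (panel$alt_freq < 0 | panel$alt_freq > 1)
  if (any(bad)) abort("panel alt_freq outside [0, 1]")
  invisible(panel)
}

#' @export
print.snp_panel <- function(x, ...) {
  cls <- table(chrom_class_of(x))
  cat(sprintf(
    "<snp_panel '%s'> %d markers (%d autosomal, %d X, %d Y)\n",
    attr(x, "name") %||% "?", nrow(x),
    cls["autosome"] %na0% 0, cls["X"] %na0% 0, cls["Y"] %na0% 0
  ))
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat(sprintf("... and %d more markers\n", nrow(x) - 5L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
`%na0%` <- function(a, b) if (is.na(a) || is.null(a)) b else as.integer(a)

#' Simulate unrelated individuals under Hardy-Weinberg equilibrium
#'
#' Draws latent true genotypes for `n` unrelated individuals. Autosomal (and
#' X in females) dosages are drawn with HWE probabilities `(1-p)^2`,
#' `2p(1-p)`, `p^2`; Y and X-in-males dosages are haploid Bernoulli(p).
#' Females carry no Y dosage (`NA`).
#'
#' @param panel a `snp_panel`.
#' @param n number of individuals (>= 1).
#' @param sex_ratio probability that an individual is male.
#' @param seed integer seed.
#' @return a `truth_set`: list with `samples` (data.frame `sample_id`, `sex`,
#'   `source`), `genotypes` (integer matrix markers x samples) and
#'   `panel_name`. Replicate samples added later share their source's
#'   genotype column. All pairs between distinct sources are unrelated.
#' @export
simulate_individuals <- function(panel, n, sex_ratio = 0.5, seed = 1) {
  validate_panel(panel)
  n <- check_count(n, "n", min = 1L)
  check_number(sex_ratio, "sex_ratio", 0, 1)
  seed <- check_count(seed, "seed")
  set.seed(seed)
  sex <- ifelse(stats::runif(n) < sex_ratio, "male", "female")
  ids <- sprintf("S%03d", seq_len(n))
  cls <- chrom_class_of(panel)
  p <- panel$alt_freq
  m <- nrow(panel)
  g <- matrix(NA_integer_, nrow = m, ncol = n,
              dimnames = list(panel$marker_id, ids))
  for (i in seq_len(n)) {
    diploid <- cls == "autosome" | (cls == "X" & sex[i] == "female")
    haploid <- cls == "Y" & sex[i] == "male" | (cls == "X" & sex[i] == "male")
    gi <- rep(NA_integer_, m)
    gi[diploid] <- stats::rbinom(sum(diploid), 2L, p[diploid])
    gi[haploid] <- stats::rbinom(sum(haploid), 1L, p[haploid])
    g[, i] <- gi
  }
  structure(
    list(
      samples = data.frame(sample_id = ids, sex = sex, source = ids,
                           stringsAsFactors = FALSE),
      genotypes = g,
      panel_name = attr(panel, "name") %||% "panel"
    ),
    class = "truth_set"
  )
}

#' Add technical replicates of an existing sample
#'
#' Replicates share the source sample's latent genotypes; every pair among
#' the source and its replicates is a same-donor pair.
#'
#' @param truth a `truth_set`.
#' @param sample_id id of an existing sample.
#' @param n_reps number of replicates to add (>= 1).
#' @return the extended `truth_set`.
#' @export
add_replicates <- function(truth, sample_id, n_reps = 1) {
  validate_truth(truth)
  n_reps <- check_count(n_reps, "n_reps", min = 1L)
  i <- match(sample_id, truth$samples$sample_id)
  if (is.na(i)) abort(sprintf("sample '%s' not found in truth set", sample_id))
  existing <- truth$samples$sample_id
  new_ids <- character(n_reps)
  k <- 1L
  for (r in seq_len(n_reps)) {
    repeat {
      cand <- sprintf("%s-rep%d", sample_id, k)
      k <- k + 1L
      if (!cand %in% existing) break
    }
    new_ids[r] <- cand
    existing <- c(existing, cand)
  }
  src <- truth$samples$source[i]
  truth$samples <- rbind(truth$samples, data.frame(
    sample_id = new_ids, sex = truth$samples$sex[i], source = src,
    stringsAsFactors = FALSE
  ))
  extra <- truth$genotypes[, rep(i, n_reps), drop = FALSE]
  colnames(extra) <- new_ids
  truth$genotypes <- cbind(truth$genotypes, extra)
  truth
}

validate_truth <- function(truth) {
  if (!inherits(truth, "truth_set")) abort("'truth' must be a truth_set")
  stopifnot(identical(colnames(truth$genotypes), truth$samples$sample_id))
  invisible(truth)
}

#' Relationship labels for all unordered sample pairs
#'
#' Pairs of samples tracing to the same source individual (replicates) are
#' `same_donor`; all others are `unrelated`. Labels are symmetric by
#' construction. With a single sample the result has zero rows.
#'
#' @param truth a `truth_set`.
#' @return data.frame with columns `sample_a`, `sample_b`, `relation`.
#' @export
pair_labels <- function(truth) {
  validate_truth(truth)
  ids <- truth$samples$sample_id
  n <- length(ids)
  if (n < 2L) {
    return(data.frame(sample_a = character(0), sample_b = character(0),
                      relation = character(0), stringsAsFactors = FALSE))
  }
  idx <- utils::combn(n, 2L)
  src <- truth$samples$source
  data.frame(
    sample_a = ids[idx[1, ]],
    sample_b = ids[idx[2, ]],
    relation = ifelse(src[idx[1, ]] == src[idx[2, ]], "same_donor", "unrelated"),
    stringsAsFactors = FALSE
  )
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf(
    "<truth_set> %d samples (%d sources) x %d markers on panel '%s'\n",
    nrow(x$samples), length(unique(x$samples$source)),
    nrow(x$genotypes), x$panel_name
  ))
  invisible(x)
}
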