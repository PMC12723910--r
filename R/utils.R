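#' Round half-up to a fixed number of decimals
#'
#' Percentages in reports are conventionally rounded half-up (87.85 -> 87.9),
#' whereas base [round()] rounds half-to-even. Full-precision values are kept
#' internally; this helper is only used when formatting reported rates.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(87.85, 1) # 87.9
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# stop() with call. = FALSE everywhere; helper keeps messages uniform
abort <- function(...) stop(..., call. = FALSE)

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("'%s' must be TRUE or FALSE", name))
  }
  x
}

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         open_min = FALSE, open_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (open_min) x > min else x >= min) &&
    (if (open_max) x < max else x <= max)
  if (!ok) {
    abort(sprintf(
      "'%s' must be a single number in %s%s, %s%s", name,
      if (open_min) "(" else "[", format(min),
      format(max), if (open_max) ")" else "]"
    ))
  }
  as.numeric(x)
}

# chromosome class from a chromosome label ("chrY", "Y" -> "Y"; "chrX" -> "X")
chrom_class <- function(chrom) {
  base <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  ifelse(toupper(base) == "Y", "Y", ifelse(toupper(base) == "X", "X", "autosome"))
}

# deterministic ordering independent of locale
order_radix <- function(...) order(..., method = "radix")
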