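#' Run an expression under a fixed RNG seed
#'
#' All stochastic operations in the package funnel randomness through this
#' helper: with a non-NULL `seed` the global RNG state is saved, the seed set,
#' and the state restored afterwards (via [withr::with_seed()]); with
#' `seed = NULL` the current RNG stream is used as-is.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed_opt <- function(seed, expr) {
  if (is.null(seed)) {
    force(expr)
  } else {
    withr::with_seed(as.integer(seed), expr)
  }
}

# round half away from zero to `digits` decimals; base round() is banker's
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

dna_bases <- c("A", "C", "G", "T")

assert_dna <- function(x, name) {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("`%s` must contain only A/C/G/T (uppercase); %d sequence(s) violate this.",
                  name, sum(bad)))
  }
  invisible(x)
}

#' Reverse-complement a DNA string
#' @param x Character vector of uppercase DNA sequences.
#' @return Character vector of reverse complements.
#' @keywords internal
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(dna_bases, n, replace = TRUE), collapse = "")
}
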