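# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force (enumeration, exhaustive scanning, naive loops)
# so that the package implementation is checked against a second route.

# Expected pooled mutant-allele read fraction at the causal site, by
# exhaustive enumeration of the F2 genotype classes selected into a bulk.
# Genotypes AA:Aa:aa segregate 1:2:1; the bulk keeps the classes whose
# phenotype matches, and the pooled allele fraction is the dosage-weighted
# mean over kept classes.
oracle_bulk_index <- function(bulk_phenotype = c("carrier", "noncarrier"),
                              mode = c("dominant", "recessive")) {
  bulk_phenotype <- match.arg(bulk_phenotype)
  mode <- match.arg(mode)
  dosage <- 0:2
  weight <- c(1, 2, 1)
  carrier <- if (mode == "dominant") dosage >= 1 else dosage == 2
  keep <- if (bulk_phenotype == "carrier") carrier else !carrier
  sum(weight[keep] * dosage[keep]) / (2 * sum(weight[keep]))
}

# Naive sliding-window recomputation (single chromosome, step in SNPs).
oracle_windows <- function(pos, delta, w, step = 1L) {
  o <- order(pos)
  pos <- pos[o]; delta <- delta[o]
  n <- length(pos)
  if (n < w) return(data.frame(center = numeric(0), mean_delta = numeric(0)))
  starts <- seq.int(1L, n - w + 1L, by = step)
  data.frame(
    center = vapply(starts, function(s) floor((pos[s] + pos[s + w - 1]) / 2), 0),
    mean_delta = vapply(starts, function(s) mean(delta[s:(s + w - 1)]), 0)
  )
}

# Exhaustive substring occurrence count over both strands, via position-by-
# position comparison (no pattern-matching library).
oracle_count_occurrences <- function(genome, pattern) {
  count_in <- function(seqs, pat) {
    k <- nchar(pat)
    sum(vapply(seqs, function(s) {
      n <- nchar(s)
      if (n < k) return(0L)
      sum(vapply(seq_len(n - k + 1L),
                 function(i) substr(s, i, i + k - 1L) == pat, logical(1)))
    }, integer(1)))
  }
  rc <- function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }
  count_in(genome, pattern) + count_in(vapply(genome, rc, ""), pattern)
}

# Expected phenotype-discordance fraction for a marker with independent
# genotype (1:2:1) and phenotype (carrier:noncarrier = 3:1 under dominance),
# by enumeration of the joint distribution.
oracle_random_discordance <- function() {
  g_prob <- c(A = 0.25, H = 0.5, B = 0.25)
  predicted_carrier <- c(A = FALSE, H = TRUE, B = TRUE)
  p_carrier <- 0.75
  sum(g_prob * ifelse(predicted_carrier, 1 - p_carrier, p_carrier))
}

# Brute-force interval intersection by sweeping integer coordinates.
oracle_intersect_sweep <- function(a, b, limit = 2000L) {
  xs <- intersect(seq(a$start, a$end), seq(b$start, b$end))
  if (length(xs) == 0L) return(NULL)
  list(start = min(xs), end = max(xs), length = length(xs))
}

# Uniform random DNA string (fixture construction only).
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Random variant tibble for filter/window fixtures.
random_variants <- function(n, seed = NULL) {
  gen <- function() {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    tibble::tibble(
      chrom = "chr2",
      pos = sort(sample.int(1e6, n)),
      ref = ref, alt = alt,
      mut_ref = rpois(n, 10), mut_alt = rpois(n, 10),
      wt_ref = rpois(n, 10) + 1L, wt_alt = rpois(n, 10)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}
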