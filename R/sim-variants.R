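#' Simulate an EMS-biased substitution spectrum
#'
#' EMS alkylates guanine, so induced point mutations are overwhelmingly
#' G:C -> A:T transitions; on the sequenced strand these appear as G>A or
#' C>T. A fraction `frac_canonical` of the emitted ref/alt pairs are drawn
#' from those two canonical transitions (equal split) and the remainder
#' uniformly from the ten other ordered substitutions.
#'
#' @param n Number of variants.
#' @param frac_canonical Fraction of canonical EMS transitions in [0, 1].
#' @param seed Optional seed.
#' @return A tibble with character columns `ref` and `alt` (`n` rows).
#' @export
#' @examples
#' simulate_ems_variants(5, frac_canonical = 1, seed = 1)
simulate_ems_variants <- function(n, frac_canonical = 0.8, seed = NULL) {
  assert_count(n, "n", min = 0L)
  assert_fraction(frac_canonical, "frac_canonical")
  if (n == 0L) {
    return(tibble(ref = character(0), alt = character(0)))
  }
  canonical <- matrix(c("G", "A", "C", "T"), nrow = 2, byrow = TRUE)
  others <- expand.grid(ref = dna_bases, alt = dna_bases,
                        stringsAsFactors = FALSE)
  others <- others[others$ref != others$alt, ]
  others <- others[!(others$ref == "G" & others$alt == "A") &
                     !(others$ref == "C" & others$alt == "T"), ]
  with_seed_opt(seed, {
    is_canon <- runif(n) < frac_canonical
    pick_canon <- sample.int(2L, n, replace = TRUE)
    pick_other <- sample.int(nrow(others), n, replace = TRUE)
    tibble(
      ref = ifelse(is_canon, canonical[pick_canon, 1], others$ref[pick_other]),
      alt = ifelse(is_canon, canonical[pick_canon, 2], others$alt[pick_other])
    )
  })
}
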