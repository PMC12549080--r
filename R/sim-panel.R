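#' Specification for a simulated accession panel
#'
#' Models a germplasm panel in which each accession carries or lacks a
#' transposon insertion and — for a subset with recorded phenotypes — shows a
#' rind phenotype whose probability depends on the insertion genotype.
#' Defaults reproduce the composition of a published melon panel in which
#' 68.68% of TE-absent accessions were mottled and 72.06% of TE-present
#' accessions were nonmottled, with 250 of 650 accessions phenotyped.
#'
#' @param n_accessions Panel size.
#' @param te_freq Probability an accession carries the insertion.
#' @param p_mottled_given_absent P(mottled | TE absent).
#' @param p_nonmottled_given_present P(nonmottled | TE present).
#' @param frac_phenotyped Fraction of accessions with a recorded phenotype.
#' @param seed Optional seed.
#' @return A list of class `"panel_sim_spec"`.
#' @export
panel_sim_spec <- function(n_accessions = 650,
                           te_freq = 68 / 250,
                           p_mottled_given_absent = 0.6868,
                           p_nonmottled_given_present = 0.7206,
                           frac_phenotyped = 250 / 650,
                           seed = NULL) {
  assert_count(n_accessions, "n_accessions", min = 1L)
  assert_fraction(te_freq, "te_freq")
  assert_fraction(p_mottled_given_absent, "p_mottled_given_absent")
  assert_fraction(p_nonmottled_given_present, "p_nonmottled_given_present")
  assert_fraction(frac_phenotyped, "frac_phenotyped")
  structure(
    list(n_accessions = as.integer(n_accessions), te_freq = te_freq,
         p_mottled_given_absent = p_mottled_given_absent,
         p_nonmottled_given_present = p_nonmottled_given_present,
         frac_phenotyped = frac_phenotyped,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "panel_sim_spec"
  )
}

#' Simulate an accession panel with genotype-dependent phenotypes
#'
#' TE status is Bernoulli(`te_freq`) per accession; a phenotype is recorded
#' for a `frac_phenotyped` subset, drawn conditionally on TE status with the
#' two configured probabilities. Unphenotyped accessions carry `NA`.
#'
#' @param spec A [panel_sim_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A tibble with columns `id`, `te_status` (`"present"`/`"absent"`)
#'   and `phenotype` (`"mottled"`/`"nonmottled"`/`NA`).
#' @export
#' @examples
#' simulate_panel(panel_sim_spec(n_accessions = 6, seed = 1))
simulate_panel <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "panel_sim_spec"))
  with_seed_opt(seed, {
    n <- spec$n_accessions
    present <- runif(n) < spec$te_freq
    phenotyped <- runif(n) < spec$frac_phenotyped
    p_mottled <- ifelse(present,
                        1 - spec$p_nonmottled_given_present,
                        spec$p_mottled_given_absent)
    mottled <- runif(n) < p_mottled
    tibble(
      id = sprintf("ACC_%04d", seq_len(n)),
      te_status = ifelse(present, "present", "absent"),
      phenotype = ifelse(phenotyped,
                         ifelse(mottled, "mottled", "nonmottled"),
                         NA_character_)
    )
  })
}
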