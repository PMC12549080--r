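#' Configuration for a simulated F2 bulk-mapping experiment
#'
#' Bundles the parameters of the emulated cross: a single chromosome carrying
#' one causal mutation, an F2 population derived by selfing the F1, and two
#' phenotype-selected bulks resequenced to a target depth. Defaults follow the
#' canonical dominant-mutant bulked-segregant design: bulks of 20 mutant-class
#' and 20 wild-class individuals sequenced at ~30x per pool, an EMS-dominated
#' mutation spectrum, and a recombination rate of about 4 cM/Mb.
#'
#' @param chrom Chromosome name used in all emitted records.
#' @param chrom_length Chromosome length in bp.
#' @param causal_pos 1-based position of the causal mutation.
#' @param n_f2 Number of F2 individuals.
#' @param bulk_size Individuals per phenotype bulk.
#' @param mean_depth Mean read depth per site per pool (Poisson, truncated
#'   at >= 1).
#' @param n_background_snps Number of segregating background variants to place
#'   when no explicit marker positions are supplied.
#' @param frac_canonical_ems Fraction of variants drawn as canonical EMS
#'   transitions (G>A or C>T).
#' @param recomb_rate Recombination rate in Morgans per bp.
#' @param dominance `"dominant"` or `"recessive"`, for the mutant allele.
#' @param carrier_phenotype Phenotype label expressed by carriers of the
#'   mutant allele under the dominance model; the complementary class is
#'   labelled with the other element of `c("mottled", "nonmottled")`.
#' @param seed Integer seed making the whole simulation reproducible, or
#'   `NULL` to use the current RNG stream.
#'
#' @return A list of class `"sim_config"`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$bulk_size
sim_config <- function(chrom = "chr2",
                       chrom_length = 1e7,
                       causal_pos = 9.5e6,
                       n_f2 = 332,
                       bulk_size = 20,
                       mean_depth = 30,
                       n_background_snps = 1000,
                       frac_canonical_ems = 0.8,
                       recomb_rate = 4e-8,
                       dominance = c("dominant", "recessive"),
                       carrier_phenotype = c("mottled", "nonmottled"),
                       seed = NULL) {
  dominance <- match.arg(dominance)
  carrier_phenotype <- match.arg(carrier_phenotype)
  assert_count(chrom_length, "chrom_length", min = 1L)
  assert_count(causal_pos, "causal_pos", min = 1L)
  if (causal_pos > chrom_length) {
    abort("`causal_pos` must lie within [1, chrom_length].")
  }
  assert_count(n_f2, "n_f2", min = 1L)
  assert_count(bulk_size, "bulk_size", min = 1L)
  if (!is.numeric(mean_depth) || mean_depth <= 0) {
    abort("`mean_depth` must be > 0.")
  }
  assert_count(n_background_snps, "n_background_snps", min = 0L)
  assert_fraction(frac_canonical_ems, "frac_canonical_ems")
  if (!is.numeric(recomb_rate) || recomb_rate < 0) {
    abort("`recomb_rate` must be >= 0 (Morgans/bp).")
  }
  structure(
    list(chrom = chrom, chrom_length = as.integer(chrom_length),
         causal_pos = as.integer(causal_pos), n_f2 = as.integer(n_f2),
         bulk_size = as.integer(bulk_size), mean_depth = mean_depth,
         n_background_snps = as.integer(n_background_snps),
         frac_canonical_ems = frac_canonical_ems, recomb_rate = recomb_rate,
         dominance = dominance, carrier_phenotype = carrier_phenotype,
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "sim_config"
  )
}

noncarrier_phenotype <- function(config) {
  setdiff(c("mottled", "nonmottled"), config$carrier_phenotype)
}

# phenotype implied by the number of mutant alleles (0/1/2)
phenotype_from_dosage <- function(dosage, config) {
  carrier <- if (config$dominance == "dominant") dosage >= 1L else dosage == 2L
  ifelse(carrier, config$carrier_phenotype, noncarrier_phenotype(config))
}

genotype_code <- function(dosage) c("AA", "Aa", "aa")[dosage + 1L]

#' Haldane map function
#'
#' Recombination fraction for a map distance `d` in Morgans, assuming no
#' crossover interference: `r = (1 - exp(-2 d)) / 2`.
#'
#' @param d Map distance in Morgans (non-negative).
#' @return Recombination fraction in [0, 0.5).
#' @export
#' @examples
#' haldane(0.1)
haldane <- function(d) {
  (1 - exp(-2 * d)) / 2
}

#' Simulate an F2 population at the causal locus
#'
#' Each individual receives two causal-locus alleles independently
#' (Mendelian 1:2:1 genotype expectation) and a phenotype that is a
#' deterministic function of the genotype under the configured dominance
#' model. `"aa"` denotes the mutant homozygote.
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `id`, `causal_genotype` (`AA`/`Aa`/`aa`,
#'   `a` = mutant allele), `dosage` (mutant-allele count) and `phenotype`.
#' @export
#' @examples
#' simulate_f2(sim_config(n_f2 = 8, seed = 1))
simulate_f2 <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_opt(config$seed, {
    dosage <- rbinom(config$n_f2, size = 2L, prob = 0.5)
    tibble(
      id = sprintf("F2_%04d", seq_len(config$n_f2)),
      causal_genotype = genotype_code(dosage),
      dosage = as.integer(dosage),
      phenotype = phenotype_from_dosage(dosage, config)
    )
  })
}

# Marker mutant-allele dosage for each individual x marker, conditional on
# the causal dosage. Each homolog carries a known causal allele; its marker
# alleles follow from a Poisson crossover process along the chromosome
# (crossovers at rate recomb_rate per bp, independent of the causal allele):
# the parental phase at a marker flips from the causal-locus phase when an
# odd number of crossovers falls between the two positions, giving the
# Haldane recombination fraction marginally while keeping nearby markers on
# one homolog jointly consistent.
marker_dosage_matrix <- function(dosage, positions, config) {
  n <- length(dosage)
  m <- length(positions)
  L <- config$chrom_length
  homolog_alleles <- function(causal_allele) {
    k <- rpois(1L, L * config$recomb_rate)
    xo <- if (k > 0) sort(runif(k, 0, L)) else numeric(0)
    parity <- (findInterval(positions, xo) -
                 findInterval(config$causal_pos, xo)) %% 2L
    (causal_allele + parity) %% 2L
  }
  out <- matrix(0L, nrow = n, ncol = m)
  for (i in seq_len(n)) {
    # dosage 1 -> one mutant and one wild homolog (assignment symmetric)
    h <- c(as.integer(dosage[i] >= 1L), as.integer(dosage[i] == 2L))
    out[i, ] <- homolog_alleles(h[1]) + homolog_alleles(h[2])
  }
  out
}

# depth ~ Poisson(mean_depth) truncated to >= 1, via inverse-CDF sampling
rpois_trunc1 <- function(n, lambda) {
  p0 <- exp(-lambda)
  u <- runif(n, min = p0, max = 1)
  pmax(1L, qpois(u, lambda))
}

select_bulks <- function(individuals, config) {
  mut <- dplyr::filter(individuals, .data$phenotype == config$carrier_phenotype)
  wt <- dplyr::filter(individuals, .data$phenotype == noncarrier_phenotype(config))
  if (nrow(mut) < config$bulk_size || nrow(wt) < config$bulk_size) {
    abort(sprintf(
      "Cannot form %d+%d bulks: %d carrier-phenotype and %d other individuals available.",
      config$bulk_size, config$bulk_size, nrow(mut), nrow(wt)))
  }
  list(mut = utils::head(mut, config$bulk_size),
       wt = utils::head(wt, config$bulk_size))
}

#' Simulate pooled allele counts for two phenotype bulks
#'
#' Forms a mutant-phenotype and a wild-phenotype bulk of `bulk_size`
#' individuals each, derives every individual's marker genotypes from its
#' causal genotype by simulating crossovers as a Poisson process along each
#' homolog (marginally the Haldane recombination fraction of the
#' marker-causal distance), and draws per-pool read counts: depth is Poisson
#' (`mean_depth`, truncated at >= 1) and the alt (mutant) count is binomial in
#' the bulk's mutant-allele frequency. Variant ref/alt bases follow the
#' configured EMS spectrum.
#'
#' @param individuals Tibble from [simulate_f2()].
#' @param config The [sim_config()] used to generate `individuals`.
#' @param marker_positions Integer vector of marker positions (bp); when
#'   `NULL`, `n_background_snps` positions are drawn uniformly on the
#'   chromosome.
#' @param seed Optional seed for this step (defaults to `config$seed + 1`
#'   when the config carries a seed, so population and counts are decoupled
#'   but jointly reproducible).
#' @return A variant tibble with columns `chrom`, `pos`, `ref`, `alt`,
#'   `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt` sorted by position.
#' @export
#' @examples
#' cfg <- sim_config(n_f2 = 60, bulk_size = 10, seed = 7)
#' f2 <- simulate_f2(cfg)
#' simulate_bulk_counts(f2, cfg, marker_positions = c(1e5, 9.5e6))
simulate_bulk_counts <- function(individuals, config, marker_positions = NULL,
                                 seed = if (is.null(config$seed)) NULL else config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(individuals) == 0L) abort("`individuals` is empty; cannot form bulks.")
  with_seed_opt(seed, {
    if (is.null(marker_positions)) {
      marker_positions <- sort(sample.int(config$chrom_length,
                                          config$n_background_snps))
    }
    marker_positions <- as.integer(sort(marker_positions))
    bulks <- select_bulks(individuals, config)
    m <- length(marker_positions)

    freq_for <- function(bulk) {
      dos <- marker_dosage_matrix(bulk$dosage, marker_positions, config)
      colSums(dos) / (2 * nrow(bulk))
    }
    f_mut <- freq_for(bulks$mut)
    f_wt <- freq_for(bulks$wt)

    depth_mut <- rpois_trunc1(m, config$mean_depth)
    depth_wt <- rpois_trunc1(m, config$mean_depth)
    alt_mut <- rbinom(m, depth_mut, f_mut)
    alt_wt <- rbinom(m, depth_wt, f_wt)

    spectrum <- simulate_ems_variants(m, config$frac_canonical_ems)
    tibble(
      chrom = config$chrom,
      pos = marker_positions,
      ref = spectrum$ref,
      alt = spectrum$alt,
      mut_ref = as.integer(depth_mut - alt_mut),
      mut_alt = as.integer(alt_mut),
      wt_ref = as.integer(depth_wt - alt_wt),
      wt_alt = as.integer(alt_wt)
    )
  })
}

# one F1 gamete per column: parental phase (0 = wild, 1 = mutant haplotype)
# at each query position, under a Poisson crossover process along the
# chromosome (Haldane model, no interference)
simulate_gamete_phases <- function(n_gametes, positions, config) {
  L <- config$chrom_length
  vapply(seq_len(n_gametes), function(i) {
    k <- rpois(1L, L * config$recomb_rate)
    xo <- if (k > 0) sort(runif(k, 0, L)) else numeric(0)
    start <- rbinom(1L, 1L, 0.5)
    (start + vapply(positions, function(p) sum(xo <= p), integer(1))) %% 2L
  }, integer(length(positions)))
}

#' Simulate a recombinant marker-genotype table
#'
#' Generates an F2 population by pairing gametes simulated as Poisson
#' crossover processes along the chromosome, so genotypes at all markers and
#' at the causal position are jointly consistent (Haldane marginals, no
#' interference). Phenotypes derive deterministically from the causal
#' genotype. The output is the long genotype/phenotype table consumed by
#' [marker_concordance()] and [delimit_interval()].
#'
#' @param config A [sim_config()]; `n_f2` individuals are generated.
#' @param marker_positions Marker positions in bp (sorted internally).
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble with columns `individual`, `phenotype`, `marker_id`,
#'   `chrom`, `pos`, `genotype` (`A` = wild homozygote, `H` = heterozygote,
#'   `B` = mutant homozygote).
#' @export
#' @examples
#' tab <- simulate_marker_table(sim_config(n_f2 = 20, seed = 3),
#'                              marker_positions = c(1e6, 5e6, 9.5e6))
#' head(tab)
simulate_marker_table <- function(config, marker_positions,
                                  seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  marker_positions <- as.integer(sort(marker_positions))
  with_seed_opt(seed, {
    query <- c(marker_positions, config$causal_pos)
    g1 <- simulate_gamete_phases(config$n_f2, query, config)
    g2 <- simulate_gamete_phases(config$n_f2, query, config)
    dos <- g1 + g2                                  # positions x individuals
    m <- length(marker_positions)
    causal_dos <- dos[m + 1L, ]
    pheno <- phenotype_from_dosage(causal_dos, config)
    ids <- sprintf("F2_%04d", seq_len(config$n_f2))
    marker_ids <- sprintf("M%03d", seq_len(m))
    tibble(
      individual = rep(ids, each = m),
      phenotype = rep(pheno, each = m),
      marker_id = rep(marker_ids, times = config$n_f2),
      chrom = config$chrom,
      pos = rep(marker_positions, times = config$n_f2),
      genotype = c("A", "H", "B")[as.vector(dos[seq_len(m), ]) + 1L]
    )
  })
}
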