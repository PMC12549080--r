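test_that("F2 genotypes segregate 1:2:1 and phenotypes follow dominance", {
  cfg <- sim_config(n_f2 = 4000, seed = 101)
  f2 <- simulate_f2(cfg)
  counts <- table(factor(f2$causal_genotype, levels = c("AA", "Aa", "aa")))
  expect_gt(chisq.test(counts, p = c(1, 2, 1) / 4)$p.value, 1e-4)
  # dominant mutant: mottled fraction ~ 3/4
  expect_equal(mean(f2$phenotype == "mottled"), 0.75,
               tolerance = 3 * sqrt(0.75 * 0.25 / 4000) / 0.75)
  # phenotype is a deterministic function of genotype
  expect_true(all((f2$dosage >= 1) == (f2$phenotype == "mottled")))

  rec <- sim_config(n_f2 = 400, dominance = "recessive", seed = 101)
  f2r <- simulate_f2(rec)
  expect_true(all((f2r$dosage == 2) == (f2r$phenotype == "mottled")))
})

test_that("simulation is reproducible under a fixed seed", {
  cfg <- sim_config(n_f2 = 50, bulk_size = 10, seed = 7)
  expect_identical(simulate_f2(cfg), simulate_f2(cfg))
  f2 <- simulate_f2(cfg)
  v1 <- simulate_bulk_counts(f2, cfg, marker_positions = c(1e5, 5e6))
  v2 <- simulate_bulk_counts(f2, cfg, marker_positions = c(1e5, 5e6))
  expect_identical(v1, v2)
})

test_that("332-individual F2 passes a 3:1 chi-square in >=90% of seeds", {
  # Monte Carlo over seeds, with the package's own segregation test as the
  # checking statistic; the pass rate should approach 1 - alpha.
  pass <- vapply(1:1000, function(s) {
    f2 <- simulate_f2(sim_config(n_f2 = 332, seed = s))
    n_mot <- sum(f2$phenotype == "mottled")
    segregation_chi2(n_mot, 332L - n_mot)$p_value >= 0.05
  }, logical(1))
  expect_gte(mean(pass), 0.90)
})

test_that("bulk allele counts match the genotype-class enumeration oracle", {
  # At the causal site the mutant (mottled) bulk contains Aa:aa = 2:1, the
  # wild bulk only AA; the oracle enumerates those classes exactly.
  expect_equal(oracle_bulk_index("carrier", "dominant"), 2 / 3)
  expect_equal(oracle_bulk_index("noncarrier", "dominant"), 0)

  idx_mut <- idx_wt <- numeric(120)
  for (s in seq_len(120)) {
    cfg <- sim_config(seed = s)
    v <- simulate_bulk_counts(simulate_f2(cfg), cfg,
                              marker_positions = cfg$causal_pos)
    idx_mut[s] <- v$mut_alt / (v$mut_ref + v$mut_alt)
    idx_wt[s] <- v$wt_alt / (v$wt_ref + v$wt_alt)
  }
  expect_equal(mean(idx_mut), 2 / 3, tolerance = 0.04)
  expect_equal(mean(idx_wt), 0, tolerance = 0.02)
})

test_that("an unlinked marker shows no delta SNP index in expectation", {
  # place the marker ~8 Morgans from the causal site so r ~ 0.5
  deltas <- vapply(seq_len(150), function(s) {
    cfg <- sim_config(chrom_length = 2e8, causal_pos = 1e6, seed = s)
    v <- simulate_bulk_counts(simulate_f2(cfg), cfg,
                              marker_positions = 1.99e8)
    v$mut_alt / (v$mut_ref + v$mut_alt) - v$wt_alt / (v$wt_ref + v$wt_alt)
  }, numeric(1))
  expect_equal(mean(deltas), 0, tolerance = 0.04)
})

test_that("per-site depth is truncated Poisson with the configured mean", {
  cfg <- sim_config(mean_depth = 30, n_background_snps = 2000, seed = 9)
  v <- simulate_bulk_counts(simulate_f2(cfg), cfg)
  depth <- c(v$mut_ref + v$mut_alt, v$wt_ref + v$wt_alt)
  expect_true(all(depth >= 1))
  expect_equal(mean(depth), 30, tolerance = 0.02)
})

test_that("bulk formation fails when a phenotype class is too small", {
  cfg <- sim_config(n_f2 = 10, bulk_size = 20, seed = 2)
  f2 <- simulate_f2(cfg)
  expect_error(simulate_bulk_counts(f2, cfg, marker_positions = 100),
               "bulks")
  expect_error(simulate_bulk_counts(f2[0, ], cfg, marker_positions = 100),
               "empty")
})

test_that("config invariants are enforced", {
  expect_error(sim_config(causal_pos = 2e7, chrom_length = 1e7), "causal_pos")
  expect_error(sim_config(frac_canonical_ems = 1.2), "frac_canonical_ems")
  expect_error(sim_config(mean_depth = 0), "mean_depth")
  expect_error(sim_config(dominance = "codominant"))
})

test_that("gamete-level marker tables have Haldane-consistent recombination", {
  # adjacent-marker recombination fraction estimated from simulated gametes
  # should match the Haldane map function of the marker spacing
  cfg <- sim_config(n_f2 = 600, chrom_length = 1e7, causal_pos = 5e6,
                    recomb_rate = 4e-8, seed = 31)
  tab <- simulate_marker_table(cfg, marker_positions = c(2e6, 8e6))
  wide <- tidyr::pivot_wider(tab[, c("individual", "marker_id", "genotype")],
                             names_from = "marker_id", values_from = "genotype")
  dos <- function(g) c(A = 0, H = 1, B = 2)[g]
  # estimate r from genotype mismatch of homozygote classes
  d1 <- dos(wide$M001); d2 <- dos(wide$M002)
  both_hom <- (d1 != 1) & (d2 != 1)
  # among double homozygotes, discordant pairs arise from double
  # recombination on mirrored gametes: P = r^2 / ((1-r)^2 + r^2)
  r <- haldane(6e6 * 4e-8)
  expected <- r^2 / ((1 - r)^2 + r^2)
  observed <- mean(d1[both_hom] != d2[both_hom])
  expect_lt(abs(observed - expected), 0.04)
})
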