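make_table <- function(genotypes, phenotypes, positions = NULL) {
  # genotypes: individuals x markers character matrix
  m <- ncol(genotypes)
  n <- nrow(genotypes)
  positions <- positions %||% seq_len(m) * 1e6
  tibble::tibble(
    individual = rep(sprintf("I%02d", seq_len(n)), each = m),
    phenotype = rep(phenotypes, each = m),
    marker_id = rep(sprintf("M%d", seq_len(m)), times = n),
    chrom = "chr2",
    pos = rep(positions, times = n),
    genotype = as.vector(t(genotypes))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a perfectly predictive marker has zero discordance", {
  g <- matrix(c("B", "H", "A", "A"), ncol = 1)
  ph <- c("mottled", "mottled", "nonmottled", "nonmottled")
  conc <- marker_concordance(make_table(g, ph))
  expect_equal(conc$n_discordant, 0L)
  expect_equal(conc$n_scored, 4L)
})

test_that("random genotypes show the enumerated discordance fraction", {
  expect_equal(oracle_random_discordance(), 3 / 8)
  n <- 4000
  withr::with_seed(19, {
    g <- matrix(sample(c("A", "H", "H", "B"), n, replace = TRUE), ncol = 1)
    ph <- sample(c("mottled", "nonmottled"), n, replace = TRUE,
                 prob = c(3, 1) / 4)
  })
  conc <- marker_concordance(make_table(g, ph))
  expect_equal(conc$n_discordant / conc$n_scored, 3 / 8, tolerance = 0.05)
})

test_that("missing data are handled per the stated rules", {
  g <- matrix(c("B", NA, NA, NA), ncol = 2)
  ph <- c("mottled", "nonmottled")
  conc <- marker_concordance(make_table(g, ph))
  expect_equal(conc$n_scored, c(1L, 0L))
  expect_true(conc$undefined[2])

  tab <- make_table(matrix("A", 2, 1), c("mottled", NA))
  expect_error(marker_concordance(tab), "phenotype")
})

test_that("delimitation returns the interval between flanking recombinant markers", {
  # five markers at 1..5 Mb with discordance (2, 1, 0, 0, 3):
  # the co-segregating block M3-M4 is bounded by M2 (2 Mb) and M5 (5 Mb)
  ph <- c(rep("mottled", 6), rep("nonmottled", 2))
  g <- rbind(
    c("A", "H", "H", "H", "A"),  # discordant at M1, M5
    c("A", "A", "H", "H", "A"),  # discordant at M1, M2, M5
    c("H", "H", "H", "H", "A"),  # discordant at M5
    c("H", "H", "H", "H", "H"),
    c("H", "H", "H", "H", "H"),
    c("H", "H", "H", "H", "H"),
    c("A", "A", "A", "A", "A"),
    c("A", "A", "A", "A", "A"))
  tab <- make_table(g, ph)
  conc <- marker_concordance(tab)
  expect_equal(conc$n_discordant, c(2L, 1L, 0L, 0L, 3L))
  out <- delimit_interval(tab)
  expect_equal(out$start, 2e6)
  expect_equal(out$end, 5e6)
  expect_false(out$open_left)
  expect_false(out$open_right)
})

test_that("a lone co-segregating marker extends to the chromosome ends", {
  g <- matrix(c("B", "H", "A", "A"), ncol = 1)
  ph <- c("mottled", "mottled", "nonmottled", "nonmottled")
  out <- delimit_interval(make_table(g, ph), chrom_length = 9e6)
  expect_equal(out$start, 1)
  expect_equal(out$end, 9e6)
  expect_true(out$open_left)
  expect_true(out$open_right)
})

test_that("pathological marker tables raise the documented errors", {
  # every marker recombinant
  g <- rbind(c("A", "A"), c("A", "A"), c("B", "B"))
  ph <- c("mottled", "mottled", "nonmottled")
  expect_error(delimit_interval(make_table(g, ph)), "No co-segregating")

  # two disjoint co-segregating blocks
  g2 <- rbind(c("B", "B", "B"), c("H", "A", "H"), c("A", "A", "A"))
  ph2 <- c("mottled", "mottled", "nonmottled")
  conc <- marker_concordance(make_table(g2, ph2))
  expect_equal(conc$n_discordant, c(0L, 1L, 0L))
  expect_error(delimit_interval(make_table(g2, ph2)), "Ambiguous")
})

test_that("delimitation recovers a planted causal interval in simulation", {
  markers <- seq(5e5, 9.75e6, by = 2.5e5)
  hits <- 0L
  n_seeds <- 25
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(n_f2 = 150, chrom_length = 1e7, causal_pos = 5e6,
                      seed = s)
    tab <- simulate_marker_table(cfg, markers)
    out <- tryCatch(delimit_interval(tab), error = function(e) NULL)
    if (!is.null(out) && out$start <= cfg$causal_pos &&
        out$end >= cfg$causal_pos) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("interval intersection follows the 1-based inclusive convention", {
  a <- tibble::tibble(chrom = "chr2", start = 100, end = 400)
  b <- tibble::tibble(chrom = "chr2", start = 300, end = 600)
  out <- intersect_intervals(a, b)
  expect_equal(out$start, 300)
  expect_equal(out$end, 400)
  expect_equal(out$length, 101)

  d1 <- tibble::tibble(chrom = "chr2", start = 1, end = 2)
  d2 <- tibble::tibble(chrom = "chr2", start = 5, end = 9)
  expect_equal(nrow(intersect_intervals(d1, d2)), 0)

  other <- tibble::tibble(chrom = "chr3", start = 1, end = 10)
  expect_error(intersect_intervals(a, other), "chromosome")
})

test_that("intersection is commutative, idempotent and bounded (sweep oracle)", {
  withr::with_seed(23, {
    for (i in 1:40) {
      a <- tibble::tibble(chrom = "chr2", start = sample(1:500, 1),
                          end = 0)
      a$end <- a$start + sample(0:500, 1)
      b <- tibble::tibble(chrom = "chr2", start = sample(1:500, 1), end = 0)
      b$end <- b$start + sample(0:500, 1)
      ab <- intersect_intervals(a, b)
      ba <- intersect_intervals(b, a)
      expect_equal(ab, ba)
      want <- oracle_intersect_sweep(a, b)
      if (is.null(want)) {
        expect_equal(nrow(ab), 0)
      } else {
        expect_equal(ab$start, want$start)
        expect_equal(ab$end, want$end)
        expect_equal(ab$length, want$length)
        expect_lte(ab$length, a$end - a$start + 1)
        expect_lte(ab$length, b$end - b$start + 1)
      }
      aa <- intersect_intervals(a, a)
      expect_equal(aa$start, a$start)
      expect_equal(aa$end, a$end)
    }
  })
})
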