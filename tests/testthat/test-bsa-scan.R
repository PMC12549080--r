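test_that("snp_index is the alt-read fraction", {
  expect_equal(snp_index(2, 8), 0.8)
  expect_equal(snp_index(10, 0), 0.0)
  expect_equal(snp_index(5, 5), 0.5)
  expect_error(snp_index(0, 0), "zero")
  expect_error(snp_index(-1, 2), "non-negative")
})

test_that("filter_ems keeps exactly the canonical transitions", {
  v <- tibble::tibble(ref = c("G", "A", "C", "C", "T"),
                      alt = c("A", "G", "T", "G", "C"),
                      pos = 1:5)
  kept <- filter_ems(v)
  expect_equal(kept$pos, c(1, 3))
  expect_equal(nrow(filter_ems(v[0, ])), 0)
  # set-comprehension oracle on random variants
  v2 <- random_variants(500, seed = 42)
  expected <- v2[(v2$ref == "G" & v2$alt == "A") |
                   (v2$ref == "C" & v2$alt == "T"), ]
  expect_equal(filter_ems(v2), expected)
})

test_that("filter_index applies the printed inclusive bounds", {
  mk <- function(iw, im) tibble::tibble(index_wt = iw, index_mut = im)
  expect_equal(nrow(filter_index(mk(0.8, 0.2))), 1)   # boundary kept
  expect_equal(nrow(filter_index(mk(0.81, 0.9))), 0)
  expect_equal(nrow(filter_index(mk(0.0, 0.19))), 0)
})

test_that("high_confidence uses strict delta and per-pool depth rules", {
  mk <- function(delta, dm, dw) {
    tibble::tibble(delta = delta, depth_mut = dm, depth_wt = dw)
  }
  expect_equal(nrow(high_confidence(mk(0.6, 30, 30))), 0)   # strict >
  expect_equal(nrow(high_confidence(mk(0.7, 11, 12))), 1)
  expect_equal(nrow(high_confidence(mk(0.9, 10, 40))), 0)   # one pool at 10
})

test_that("ems and index filters commute and are idempotent", {
  v <- random_variants(300, seed = 13)
  pts <- snp_index_points(v)
  th <- scan_thresholds()
  a <- filter_index(filter_ems(pts), th)
  b <- filter_ems(filter_index(pts, th))
  expect_equal(a, b)
  expect_equal(filter_ems(filter_ems(v)), filter_ems(v))
  expect_equal(filter_index(filter_index(pts, th), th), filter_index(pts, th))
})

test_that("sliding windows match the specification on simple cases", {
  pts <- tibble::tibble(chrom = "chr2", pos = c(100, 200, 300, 400, 500),
                        delta = rep(0.5, 5))
  w <- sliding_windows(pts)
  expect_equal(nrow(w), 1)
  expect_equal(w$center, 300)
  expect_equal(w$mean_delta, 0.5)
  expect_equal(w$n_snps, 5L)

  pts6 <- tibble::tibble(chrom = "chr2", pos = seq(100, 600, by = 100),
                         delta = runif(6))
  expect_equal(nrow(sliding_windows(pts6)), 2)

  few <- pts6[1:3, ]
  expect_warning(out <- sliding_windows(few), "fewer")
  expect_equal(nrow(out), 0)
})

test_that("window means equal the brute-force oracle on random fixtures", {
  for (s in 1:50) {
    n <- sample(5:60, 1)
    pts <- withr::with_seed(s, tibble::tibble(
      chrom = "chr2", pos = sort(sample.int(1e6, n)), delta = runif(n, -1, 1)))
    got <- sliding_windows(pts)
    want <- oracle_windows(pts$pos, pts$delta, 5L)
    expect_equal(got$center, want$center)
    expect_equal(got$mean_delta, want$mean_delta, tolerance = 1e-12)
    expect_equal(nrow(got), max(0, n - 5 + 1))
  }
})

test_that("window means respect member-delta bounds per window", {
  pts <- random_variants(200, seed = 77)
  pp <- snp_index_points(pts)
  w <- sliding_windows(pp)
  for (i in seq_len(nrow(w))) {
    members <- pp$delta[pp$pos >= w$pos_first[i] & pp$pos <= w$pos_last[i]]
    expect_gte(w$mean_delta[i], min(members))
    expect_lte(w$mean_delta[i], max(members))
  }
})

test_that("call_regions merges by gap and ranks by support", {
  hc <- tibble::tibble(chrom = "chr2", pos = c(1e6, 1.5e6, 9e6),
                       delta = c(0.7, 0.8, 0.9))
  regions <- call_regions(hc, scan_thresholds(region_merge_gap = 1e6))
  expect_equal(nrow(regions), 2)
  expect_equal(regions$start, c(1e6, 9e6))
  expect_equal(regions$end, c(1.5e6, 9e6))
  expect_equal(nrow(call_regions(hc[0, ])), 0)
})

test_that("the top candidate region contains a planted causal locus", {
  hits <- 0L
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(seed = s)
    v <- simulate_bulk_counts(simulate_f2(cfg), cfg,
                              marker_positions = seq(5000, cfg$chrom_length,
                                                     by = 10000))
    scan <- suppressMessages(bsa_scan(v))
    top <- top_region(scan)
    peak <- scan$windows$center[which.max(scan$windows$mean_delta)]
    ok <- nrow(top) == 1 && top$start <= cfg$causal_pos &&
      top$end >= cfg$causal_pos && peak >= top$start && peak <= top$end
    hits <- hits + ok
  }
  expect_gte(hits / n_seeds, 0.9)
})

test_that("scan indices stay within their ranges", {
  v <- random_variants(400, seed = 3)
  pts <- snp_index_points(v)
  expect_true(all(pts$index_mut >= 0 & pts$index_mut <= 1))
  expect_true(all(pts$index_wt >= 0 & pts$index_wt <= 1))
  expect_true(all(pts$delta >= -1 & pts$delta <= 1))
  expect_equal(pts$delta, pts$index_mut - pts$index_wt)
})

test_that("zero-depth sites are dropped with a message", {
  v <- tibble::tibble(chrom = "chr2", pos = 1:2, ref = "G", alt = "A",
                      mut_ref = c(0L, 5L), mut_alt = c(0L, 5L),
                      wt_ref = c(3L, 3L), wt_alt = c(1L, 1L))
  expect_message(pts <- snp_index_points(v), "zero depth")
  expect_equal(nrow(pts), 1)
})
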