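#' Thresholds for the delta SNP-index scan
#'
#' The scan retains EMS-type variants whose SNP index is at most
#' `wt_index_max` in the wild-phenotype pool and at least `mut_index_min` in
#' the mutant-phenotype pool (inclusive bounds), and calls a site
#' high-confidence when its delta SNP index strictly exceeds `delta_min` with
#' both pool depths strictly above `depth_min`. Windows average `window_snps`
#' consecutive SNPs, advancing by `window_step_snps` SNPs; high-confidence
#' sites closer than `region_merge_gap` are merged into candidate regions.
#'
#' @param wt_index_max Maximum SNP index allowed in the wild-type pool.
#' @param mut_index_min Minimum SNP index required in the mutant pool.
#' @param delta_min High-confidence delta SNP-index threshold (strict).
#' @param depth_min High-confidence per-pool depth threshold (strict).
#' @param window_snps SNPs per sliding window.
#' @param window_step_snps Step between consecutive windows, in SNPs.
#' @param region_merge_gap Maximum gap (bp) merged into one candidate region.
#' @return A list of class `"scan_thresholds"`.
#' @export
scan_thresholds <- function(wt_index_max = 0.8, mut_index_min = 0.2,
                            delta_min = 0.6, depth_min = 10,
                            window_snps = 5, window_step_snps = 1,
                            region_merge_gap = 1e6) {
  assert_fraction(wt_index_max, "wt_index_max")
  assert_fraction(mut_index_min, "mut_index_min")
  if (!is.numeric(delta_min) || delta_min < -1 || delta_min > 1) {
    abort("`delta_min` must be in [-1, 1].")
  }
  assert_count(depth_min, "depth_min", min = 0L)
  assert_count(window_snps, "window_snps", min = 1L)
  assert_count(window_step_snps, "window_step_snps", min = 1L)
  if (!is.numeric(region_merge_gap) || region_merge_gap < 0) {
    abort("`region_merge_gap` must be >= 0.")
  }
  structure(
    list(wt_index_max = wt_index_max, mut_index_min = mut_index_min,
         delta_min = delta_min, depth_min = as.integer(depth_min),
         window_snps = as.integer(window_snps),
         window_step_snps = as.integer(window_step_snps),
         region_merge_gap = region_merge_gap),
    class = "scan_thresholds"
  )
}

#' SNP index of a pool
#'
#' The fraction of reads at a site that carry the alternative (mutant)
#' allele: `alt / (ref + alt)`. Undefined at zero depth.
#'
#' @param ref_count,alt_count Non-negative read counts (vectorised).
#' @return Numeric vector of fractions in [0, 1].
#' @export
#' @examples
#' snp_index(2, 8)
snp_index <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0)) {
    abort("Read counts must be non-negative.")
  }
  total <- ref_count + alt_count
  if (any(total < 1)) {
    abort("SNP index undefined at zero total depth.")
  }
  alt_count / total
}

#' Per-site SNP indices and delta SNP index
#'
#' Computes, for each variant, the SNP index in the mutant-phenotype and
#' wild-phenotype pools and their difference `delta = index_mut - index_wt`
#' (positive at the causal locus under this sign convention). Sites where
#' either pool has zero depth are dropped with a message.
#'
#' @param variants Variant tibble (`chrom`, `pos`, `ref`, `alt`, `mut_ref`,
#'   `mut_alt`, `wt_ref`, `wt_alt`), as from [simulate_bulk_counts()] or
#'   [read_variants()].
#' @return A tibble adding `index_mut`, `index_wt`, `delta`, `depth_mut`,
#'   `depth_wt`.
#' @export
#' @examples
#' v <- tibble::tibble(chrom = "chr2", pos = 100, ref = "G", alt = "A",
#'                     mut_ref = 2L, mut_alt = 8L, wt_ref = 10L, wt_alt = 0L)
#' snp_index_points(v)
snp_index_points <- function(variants) {
  depth_mut <- variants$mut_ref + variants$mut_alt
  depth_wt <- variants$wt_ref + variants$wt_alt
  zero <- depth_mut == 0L | depth_wt == 0L
  if (any(zero)) {
    inform(sprintf("Dropping %d site(s) with zero depth in a pool.", sum(zero)))
  }
  out <- variants[!zero, , drop = FALSE]
  out$index_mut <- snp_index(out$mut_ref, out$mut_alt)
  out$index_wt <- snp_index(out$wt_ref, out$wt_alt)
  out$delta <- out$index_mut - out$index_wt
  out$depth_mut <- as.integer(out$mut_ref + out$mut_alt)
  out$depth_wt <- as.integer(out$wt_ref + out$wt_alt)
  as_tibble(out)
}

#' Keep canonical EMS-induced transitions
#'
#' Retains exactly the variants whose (ref, alt) pair is G>A or C>T — the
#' transitions EMS mutagenesis produces on the sequenced strand — preserving
#' input order.
#'
#' @param variants Tibble with character columns `ref` and `alt`.
#' @return The filtered tibble.
#' @export
#' @examples
#' filter_ems(tibble::tibble(ref = c("G", "A"), alt = c("A", "G")))
filter_ems <- function(variants) {
  keep <- (variants$ref == "G" & variants$alt == "A") |
    (variants$ref == "C" & variants$alt == "T")
  as_tibble(variants[keep, , drop = FALSE])
}

#' Apply the per-pool SNP-index filter
#'
#' Keeps sites with `index_wt <= wt_index_max` and
#' `index_mut >= mut_index_min` (both bounds inclusive), removing sites whose
#' index pattern is inconsistent with a mutation segregating in the
#' mutant-phenotype pool.
#'
#' @param points Tibble from [snp_index_points()].
#' @param thresholds A [scan_thresholds()].
#' @return The filtered tibble.
#' @export
filter_index <- function(points, thresholds = scan_thresholds()) {
  keep <- points$index_wt <= thresholds$wt_index_max &
    points$index_mut >= thresholds$mut_index_min
  as_tibble(points[keep, , drop = FALSE])
}

#' Keep high-confidence candidate sites
#'
#' A site is high-confidence when its delta SNP index strictly exceeds
#' `delta_min` and both pool depths strictly exceed `depth_min`.
#'
#' @inheritParams filter_index
#' @return The filtered tibble.
#' @export
high_confidence <- function(points, thresholds = scan_thresholds()) {
  keep <- points$delta > thresholds$delta_min &
    points$depth_mut > thresholds$depth_min &
    points$depth_wt > thresholds$depth_min
  as_tibble(points[keep, , drop = FALSE])
}

#' Sliding-window means of the delta SNP index
#'
#' Windows of `window_snps` consecutive SNPs (per chromosome, sorted by
#' position) advance by `window_step_snps` SNPs. Each window reports the
#' arithmetic mean delta and a center at the floor of the midpoint between
#' its first and last SNP.
#'
#' @inheritParams filter_index
#' @return A tibble with `chrom`, `center`, `mean_delta`, `n_snps`,
#'   `pos_first`, `pos_last`; empty (with a warning) when a chromosome has
#'   fewer SNPs than the window size.
#' @export
#' @examples
#' pts <- tibble::tibble(chrom = "chr2", pos = c(100, 200, 300, 400, 500),
#'                       delta = rep(0.5, 5))
#' sliding_windows(pts)
sliding_windows <- function(points, thresholds = scan_thresholds()) {
  w <- thresholds$window_snps
  step <- thresholds$window_step_snps
  empty <- tibble(chrom = character(0), center = numeric(0),
                  mean_delta = numeric(0), n_snps = integer(0),
                  pos_first = numeric(0), pos_last = numeric(0))
  if (nrow(points) == 0L) {
    warn("No SNPs supplied; no windows computed.")
    return(empty)
  }
  points <- dplyr::arrange(points, .data$chrom, .data$pos)
  out <- dplyr::group_modify(dplyr::group_by(points, .data$chrom), function(d, key) {
    n <- nrow(d)
    if (n < w) {
      warn(sprintf("Chromosome %s has %d SNP(s), fewer than the window size %d.",
                   key$chrom, n, w))
      return(empty[, setdiff(names(empty), "chrom")])
    }
    starts <- seq.int(1L, n - w + 1L, by = step)
    # cumulative sums give every window mean in one pass
    cs <- cumsum(c(0, d$delta))
    tibble(
      center = floor((d$pos[starts] + d$pos[starts + w - 1L]) / 2),
      mean_delta = (cs[starts + w] - cs[starts]) / w,
      n_snps = w,
      pos_first = d$pos[starts],
      pos_last = d$pos[starts + w - 1L]
    )
  })
  dplyr::ungroup(out)
}

#' Merge high-confidence sites into candidate regions
#'
#' Consecutive high-confidence sites on the same chromosome whose gap is at
#' most `region_merge_gap` bp are merged into maximal intervals spanning
#' their first and last positions. Regions are ranked by supporting SNP
#' count (ties by mean delta).
#'
#' @param hc_points High-confidence tibble from [high_confidence()].
#' @inheritParams filter_index
#' @return An interval tibble: `chrom`, `start`, `end`, `n_snps`,
#'   `mean_delta`, `label`, sorted by chromosome and start.
#' @export
call_regions <- function(hc_points, thresholds = scan_thresholds()) {
  if (nrow(hc_points) == 0L) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  n_snps = integer(0), mean_delta = numeric(0),
                  label = character(0)))
  }
  pts <- dplyr::arrange(hc_points, .data$chrom, .data$pos)
  pts <- dplyr::group_by(pts, .data$chrom)
  pts <- dplyr::mutate(pts,
    new_run = c(TRUE, diff(.data$pos) > thresholds$region_merge_gap),
    run = cumsum(.data$new_run))
  out <- dplyr::summarise(dplyr::group_by(pts, .data$chrom, .data$run),
    start = min(.data$pos), end = max(.data$pos),
    n_snps = dplyr::n(), mean_delta = mean(.data$delta), .groups = "drop")
  out <- dplyr::arrange(out, .data$chrom, .data$start)
  out$run <- NULL
  out$label <- sprintf("region_%02d", seq_len(nrow(out)))
  out
}

#' Run the full delta SNP-index scan
#'
#' Chains the scan stages: per-site indices, EMS transition filter, per-pool
#' index filter, sliding windows, high-confidence site selection, and
#' candidate-region calling.
#'
#' @param variants Variant tibble (see [snp_index_points()]).
#' @param thresholds A [scan_thresholds()].
#' @return An object of class `"bsa_scan"`: a list with tibbles `points`
#'   (filtered per-site indices), `windows`, `hc_points` and `regions`, plus
#'   the thresholds used.
#' @export
#' @examples
#' cfg <- sim_config(n_f2 = 60, bulk_size = 10, n_background_snps = 200,
#'                   seed = 11)
#' scan <- bsa_scan(simulate_bulk_counts(simulate_f2(cfg), cfg))
#' scan$regions
bsa_scan <- function(variants, thresholds = scan_thresholds()) {
  pts <- snp_index_points(filter_ems(variants))
  pts <- filter_index(pts, thresholds)
  wins <- suppressWarnings(sliding_windows(pts, thresholds))
  hc <- high_confidence(pts, thresholds)
  regions <- call_regions(hc, thresholds)
  structure(
    list(points = pts, windows = wins, hc_points = hc, regions = regions,
         thresholds = thresholds),
    class = "bsa_scan"
  )
}

#' @export
print.bsa_scan <- function(x, ...) {
  cat(sprintf("<bsa_scan> %d filtered SNPs, %d windows, %d high-confidence SNPs, %d candidate region(s)\n",
              nrow(x$points), nrow(x$windows), nrow(x$hc_points),
              nrow(x$regions)))
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}

#' @rdname bsa_scan
#' @param x A `bsa_scan` object.
#' @param ... Unused.
#' @export
tidy.bsa_scan <- function(x, ...) {
  x$regions
}

#' @rdname bsa_scan
#' @export
glance.bsa_scan <- function(x, ...) {
  tibble(
    n_snps = nrow(x$points),
    n_windows = nrow(x$windows),
    n_hc_snps = nrow(x$hc_points),
    n_regions = nrow(x$regions),
    peak_center = if (nrow(x$windows)) x$windows$center[which.max(x$windows$mean_delta)] else NA_real_,
    peak_mean_delta = if (nrow(x$windows)) max(x$windows$mean_delta) else NA_real_
  )
}

#' Candidate region ranked best by supporting evidence
#'
#' @param scan A `bsa_scan` object.
#' @return One-row interval tibble (or zero rows if no region was called).
#' @export
top_region <- function(scan) {
  r <- scan$regions
  if (nrow(r) == 0L) return(r)
  r[order(-r$n_snps, -r$mean_delta), ][1, , drop = FALSE]
}
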