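#' Specification for a simulated transposon-junction sequencing experiment
#'
#' Describes one sample: a locus with two unique flanking sequences, an
#' optional transposon inserted between them, and a paired-end short-read
#' library over the resulting haplotype. Defaults mirror a typical Illumina
#' library (150-bp reads, 350-bp inserts) over a 4231-bp element with 200-bp
#' unique flanks.
#'
#' @param flank_len Flank length in bp (>= 1).
#' @param te_len Transposon length in bp (>= 0).
#' @param read_len Read length in bp (>= 2).
#' @param insert_size Fragment (insert) size in bp; must be >= `read_len`.
#' @param n_read_pairs Number of read pairs to emit.
#' @param te_present Logical ground truth: is the element inserted?
#' @param bg_len Extra background sequence on each side of the flanks, bp.
#' @param seed Optional seed.
#' @return A list of class `"te_sim_spec"`.
#' @export
te_sim_spec <- function(flank_len = 200, te_len = 4231, read_len = 150,
                        insert_size = 350, n_read_pairs = 500,
                        te_present = TRUE, bg_len = 500, seed = NULL) {
  assert_count(flank_len, "flank_len", min = 1L)
  assert_count(te_len, "te_len", min = 0L)
  assert_count(read_len, "read_len", min = 2L)
  assert_count(insert_size, "insert_size", min = 1L)
  if (insert_size < read_len) abort("`insert_size` must be >= `read_len`.")
  assert_count(n_read_pairs, "n_read_pairs", min = 0L)
  assert_count(bg_len, "bg_len", min = 0L)
  structure(
    list(flank_len = as.integer(flank_len), te_len = as.integer(te_len),
         read_len = as.integer(read_len), insert_size = as.integer(insert_size),
         n_read_pairs = as.integer(n_read_pairs),
         te_present = isTRUE(te_present), bg_len = as.integer(bg_len),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "te_sim_spec"
  )
}

#' Build a transposon insertion locus
#'
#' Constructs the sequences of one insertion locus from random DNA: unique
#' left/right flanks embedded in background sequence, the inserted element,
#' the TE-absent reference and the TE-present haplotype. Flank uniqueness in
#' the reference is verified with [check_flank_uniqueness()] (the locus is
#' resampled on the rare collision). Sharing one locus across samples lets a
#' panel be genotyped against a single [insertion_site()].
#'
#' @param spec A [te_sim_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @return A list of class `"te_locus"`: `reference`, `hap_present`,
#'   `hap_absent`, `te_seq` and `site`.
#' @export
te_locus <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "te_sim_spec"))
  with_seed_opt(seed, {
    for (attempt in 1:20) {
      bg_l <- random_dna(spec$bg_len)
      bg_r <- random_dna(spec$bg_len)
      left <- random_dna(spec$flank_len)
      right <- random_dna(spec$flank_len)
      reference <- paste0(bg_l, left, right, bg_r)
      site <- insertion_site(
        chrom = "chr2",
        junction_pos = nchar(bg_l) + nchar(left),
        left_flank = left, right_flank = right, te_len = spec$te_len
      )
      uniq <- check_flank_uniqueness(reference, site)
      if (all(uniq$left, uniq$right)) break
    }
    if (!all(uniq$left, uniq$right)) {
      abort("Failed to construct unique flanks; increase flank_len.")
    }
    te_seq <- if (spec$te_len > 0) random_dna(spec$te_len) else ""
    site$te_left <- substr(te_seq, 1L, min(nchar(te_seq), 200L))
    site$te_right <- substr(te_seq, max(1L, nchar(te_seq) - 199L), nchar(te_seq))
    structure(
      list(reference = reference,
           hap_present = paste0(bg_l, left, te_seq, right, bg_r),
           hap_absent = reference, te_seq = te_seq, site = site),
      class = "te_locus"
    )
  })
}

#' Simulate reads over a transposon insertion junction
#'
#' Samples `n_read_pairs` paired-end reads uniformly along the haplotype of
#' a [te_locus()] — with the element inserted when `te_present`, without it
#' otherwise. The second mate is reverse-complemented, as in a standard FR
#' library. When no locus is supplied a fresh one is built from `spec`.
#'
#' @param spec A [te_sim_spec()].
#' @param seed Optional seed overriding `spec$seed`.
#' @param locus Optional [te_locus()] shared across samples.
#' @return A list with elements `reference` (TE-absent reference sequence),
#'   `haplotype` (sequenced haplotype, with the TE when `te_present`),
#'   `reads` (character vector, both mates), `site` (an [insertion_site()]
#'   carrying the flank and TE-end sequences) and `truth` (logical
#'   `te_present`).
#' @export
#' @examples
#' sim <- simulate_te_reads(te_sim_spec(n_read_pairs = 50, seed = 2))
#' sim$truth
#' length(sim$reads)
simulate_te_reads <- function(spec, seed = spec$seed, locus = NULL) {
  stopifnot(inherits(spec, "te_sim_spec"))
  with_seed_opt(seed, {
    if (is.null(locus)) locus <- te_locus(spec, seed = NULL)
    reference <- locus$reference
    site <- locus$site
    haplotype <- if (spec$te_present) locus$hap_present else locus$hap_absent
    hap_len <- nchar(haplotype)
    if (spec$read_len > hap_len) {
      abort("`read_len` exceeds the haplotype length.")
    }
    frag <- min(spec$insert_size, hap_len)
    reads <- character(0)
    if (spec$n_read_pairs > 0) {
      start <- sample.int(hap_len - frag + 1L, spec$n_read_pairs, replace = TRUE)
      r1 <- substring(haplotype, start, start + spec$read_len - 1L)
      r2 <- revcomp(substring(haplotype, start + frag - spec$read_len,
                              start + frag - 1L))
      reads <- as.character(rbind(r1, r2))
    }
    list(reference = reference, haplotype = haplotype, reads = reads,
         site = site, truth = spec$te_present)
  })
}
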