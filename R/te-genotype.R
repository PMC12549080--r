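#' Describe a transposon insertion site
#'
#' Coordinates and flanking sequences of one insertion locus.
#' `junction_pos` is the reference position immediately left of the
#' insertion point in the TE-absent reference. `te_left`/`te_right` carry
#' the first and last bases of the inserted element, needed to genotype the
#' TE-present junctions.
#'
#' @param chrom Chromosome name.
#' @param junction_pos 1-based position left of the insertion point.
#' @param left_flank,right_flank Uppercase DNA flanking sequences.
#' @param te_len Element length in bp.
#' @param te_left,te_right Leading/trailing element sequence (optional until
#'   TE-present junction genotyping is needed).
#' @return A list of class `"insertion_site"`.
#' @export
insertion_site <- function(chrom, junction_pos, left_flank, right_flank,
                           te_len, te_left = NULL, te_right = NULL) {
  assert_dna(c(left_flank, right_flank), "flanks")
  structure(
    list(chrom = chrom, junction_pos = as.integer(junction_pos),
         left_flank = left_flank, right_flank = right_flank,
         te_len = as.integer(te_len), te_left = te_left, te_right = te_right),
    class = "insertion_site"
  )
}

#' Check that insertion-site flanks are unique in a genome
#'
#' Counts occurrences of each flank on both strands of the genome (forward
#' sequence and its reverse complement); a flank is unique iff the total is
#' exactly one. Multi-sequence genomes are searched sequence by sequence. A
#' repetitive flank makes junction-read evidence unattributable, so
#' genotyping requires both flanks unique.
#'
#' @param genome Character vector of uppercase DNA sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param site An [insertion_site()].
#' @return A list: `left` and `right` logical flags, plus `n_left`/`n_right`
#'   occurrence totals.
#' @export
check_flank_uniqueness <- function(genome, site) {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  if (length(genome) == 0L || any(!nzchar(genome))) {
    abort("`genome` must be non-empty.")
  }
  assert_dna(c(site$left_flank, site$right_flank), "flanks")
  subject <- Biostrings::DNAStringSet(genome)
  count_both_strands <- function(flank) {
    fwd <- sum(Biostrings::vcountPattern(flank, subject))
    rev <- sum(Biostrings::vcountPattern(revcomp(flank), subject))
    fwd + rev
  }
  n_left <- count_both_strands(site$left_flank)
  n_right <- count_both_strands(site$right_flank)
  list(left = n_left == 1L, right = n_right == 1L,
       n_left = n_left, n_right = n_right)
}

junction_kmers <- function(site, min_overlap, junction = c("present", "absent")) {
  junction <- match.arg(junction)
  take_suffix <- function(s) substr(s, nchar(s) - min_overlap + 1L, nchar(s))
  take_prefix <- function(s) substr(s, 1L, min_overlap)
  if (junction == "absent") {
    return(paste0(take_suffix(site$left_flank), take_prefix(site$right_flank)))
  }
  if (is.null(site$te_left) || is.null(site$te_right)) {
    abort("TE-present junction genotyping needs `te_left`/`te_right` on the site.")
  }
  c(paste0(take_suffix(site$left_flank), take_prefix(site$te_left)),
    paste0(take_suffix(site$te_right), take_prefix(site$right_flank)))
}

#' Count breakpoint-spanning reads
#'
#' A read spans a junction when it contains, as an exact substring in either
#' orientation, the `min_overlap` bases on each side of that junction. In
#' `junction = "present"` mode (the default, evidencing the insertion) both
#' TE-flank junctions are interrogated and a read matching either is
#' counted once; `junction = "absent"` mode uses the reference junction
#' (left-flank suffix joined to right-flank prefix).
#'
#' @param reads Character vector of uppercase DNA reads.
#' @param site An [insertion_site()].
#' @param min_overlap Bases required on each side of the junction
#'   (default 20).
#' @param junction `"present"` or `"absent"` junction mode.
#' @return Integer count of spanning reads.
#' @export
#' @examples
#' sim <- simulate_te_reads(te_sim_spec(n_read_pairs = 200, seed = 4))
#' count_spanning_reads(sim$reads, sim$site)
count_spanning_reads <- function(reads, site, min_overlap = 20,
                                 junction = c("present", "absent")) {
  junction <- match.arg(junction)
  min_overlap <- assert_count(min_overlap, "min_overlap", min = 1L)
  if (length(reads) == 0L) return(0L)
  if (min_overlap * 2L > max(nchar(reads))) {
    abort("`min_overlap` is larger than half the read length; no read can span.")
  }
  kmers <- junction_kmers(site, min_overlap, junction)
  patterns <- unique(c(kmers, revcomp(kmers)))
  hit <- rep(FALSE, length(reads))
  for (p in patterns) {
    hit <- hit | stringr::str_detect(reads, stringr::fixed(p))
  }
  sum(hit)
}

#' Classify a sample's TE genotype from spanning-read count
#'
#' Two or more breakpoint-spanning reads classify the sample as containing
#' the element; one or none as lacking it. Absence is therefore the
#' no-evidence class: undersequenced carriers drift toward "absent".
#'
#' @param n_spanning Non-negative integer vector of spanning-read counts.
#' @return Character vector, `"present"` or `"absent"`.
#' @export
#' @examples
#' classify_te(0:3)
classify_te <- function(n_spanning) {
  if (any(n_spanning < 0)) abort("`n_spanning` must be >= 0.")
  ifelse(n_spanning >= 2, "present", "absent")
}

#' Genotype a panel of samples for a TE insertion
#'
#' Counts breakpoint-spanning reads per sample and applies the two-read
#' classification rule.
#'
#' @param samples Named list mapping sample id to a character vector of
#'   reads.
#' @param site An [insertion_site()].
#' @inheritParams count_spanning_reads
#' @return An object of class `"te_panel"`: list with `calls` (tibble
#'   `sample_id`, `n_spanning`, `call`) and `summary` (tibble `n_samples`,
#'   `n_present`, `n_absent`).
#' @export
#' @examples
#' sims <- lapply(1:3, function(i)
#'   simulate_te_reads(te_sim_spec(n_read_pairs = 150, te_present = i > 1,
#'                                 seed = i)))
#' panel <- genotype_te_panel(setNames(lapply(sims, `[[`, "reads"),
#'                                     paste0("S", 1:3)), sims[[2]]$site)
#' panel$summary
genotype_te_panel <- function(samples, site, min_overlap = 20,
                              junction = "present") {
  if (length(samples) == 0L) abort("`samples` must contain at least one sample.")
  ids <- names(samples)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    abort("`samples` must be a named list (sample_id -> reads).")
  }
  if (anyDuplicated(ids)) abort("Duplicate sample ids in `samples`.")
  n_spanning <- vapply(samples, function(r) {
    as.integer(count_spanning_reads(r, site, min_overlap, junction))
  }, integer(1))
  calls <- tibble(sample_id = ids, n_spanning = unname(n_spanning),
                  call = classify_te(unname(n_spanning)))
  structure(
    list(calls = calls,
         summary = tibble(n_samples = nrow(calls),
                          n_present = sum(calls$call == "present"),
                          n_absent = sum(calls$call == "absent"))),
    class = "te_panel"
  )
}

#' @export
print.te_panel <- function(x, ...) {
  cat(sprintf("<te_panel> %d samples: %d TE-present, %d TE-absent\n",
              x$summary$n_samples, x$summary$n_present, x$summary$n_absent))
  invisible(x)
}

#' @rdname genotype_te_panel
#' @param x A `te_panel` object.
#' @param ... Unused.
#' @export
tidy.te_panel <- function(x, ...) x$calls

#' @rdname genotype_te_panel
#' @export
glance.te_panel <- function(x, ...) x$summary
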