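#' Dominance model mapping marker genotypes to expected phenotypes
#'
#' Defines the total map from the genotype codes `A` (recurrent-parent
#' homozygote), `H` (heterozygote) and `B` (donor/mutant homozygote) to an
#' expected phenotype: `B` always shows `carrier_phenotype`; `H` shows it iff
#' the mutant allele is dominant.
#'
#' @param carrier_phenotype Phenotype of mutant-allele carriers.
#' @param mode `"dominant"` or `"recessive"` for the mutant allele.
#' @return A list of class `"dominance_model"`.
#' @export
#' @examples
#' expected_phenotype(c("A", "H", "B"), dominance_model())
dominance_model <- function(carrier_phenotype = c("mottled", "nonmottled"),
                            mode = c("dominant", "recessive")) {
  structure(
    list(carrier_phenotype = match.arg(carrier_phenotype),
         mode = match.arg(mode)),
    class = "dominance_model"
  )
}

#' @rdname dominance_model
#' @param genotype Character vector of codes in `A`/`H`/`B` (`NA` allowed).
#' @param model A `dominance_model`.
#' @export
expected_phenotype <- function(genotype, model = dominance_model()) {
  other <- setdiff(c("mottled", "nonmottled"), model$carrier_phenotype)
  carrier <- if (model$mode == "dominant") {
    genotype %in% c("H", "B")
  } else {
    genotype == "B"
  }
  out <- ifelse(carrier, model$carrier_phenotype, other)
  out[is.na(genotype)] <- NA_character_
  out
}

#' Phenotype discordance per marker
#'
#' For every marker, counts the individuals whose observed phenotype differs
#' from the phenotype their marker genotype predicts under the dominance
#' model. Individuals with a missing genotype at a marker are excluded from
#' that marker's denominator; a marker scored in nobody is flagged
#' undefined. A zero-discordance marker co-segregates with the trait.
#'
#' @param table Long genotype table with columns `individual`, `phenotype`,
#'   `marker_id`, `chrom`, `pos`, `genotype` (as from
#'   [simulate_marker_table()] or [read_marker_table()]).
#' @param model A [dominance_model()].
#' @return A tibble per marker: `marker_id`, `chrom`, `pos`, `n_scored`,
#'   `n_discordant`, `undefined` (TRUE when no individual was scored).
#' @export
marker_concordance <- function(table, model = dominance_model()) {
  if (any(is.na(table$phenotype))) {
    abort("Every individual must have an observed phenotype.")
  }
  tab <- dplyr::mutate(table,
    expected = expected_phenotype(.data$genotype, model),
    scored = !is.na(.data$genotype),
    discordant = .data$scored & .data$expected != .data$phenotype)
  out <- dplyr::summarise(
    dplyr::group_by(tab, .data$marker_id, .data$chrom, .data$pos),
    n_scored = sum(.data$scored),
    n_discordant = sum(.data$discordant),
    .groups = "drop")
  out$undefined <- out$n_scored == 0L
  dplyr::arrange(out, .data$chrom, .data$pos)
}

#' Delimit the causal interval from recombinant marker data
#'
#' Finds the contiguous block of markers that co-segregate with the
#' phenotype (discordance <= `max_discordant`) and returns the open interval
#' bounded by the nearest flanking markers that do show recombination with
#' the phenotype. When no discordant marker flanks the block on a side, that
#' end extends to the chromosome end (position 1 or `chrom_length`) and is
#' flagged.
#'
#' @inheritParams marker_concordance
#' @param max_discordant Maximum discordant individuals for a marker to count
#'   as co-segregating (default 0).
#' @param chrom_length Optional chromosome length used when the block reaches
#'   the last marker; defaults to the last marker position.
#' @return A one-row interval tibble: `chrom`, `start`, `end`, `label`,
#'   `open_left`, `open_right` (TRUE when unbounded by a recombinant marker
#'   on that side).
#' @export
#' @examples
#' tab <- simulate_marker_table(sim_config(n_f2 = 100, seed = 5),
#'                              marker_positions = seq(5e5, 9.5e6, by = 5e5))
#' delimit_interval(tab)
delimit_interval <- function(table, model = dominance_model(),
                             max_discordant = 0, chrom_length = NULL) {
  conc <- marker_concordance(table, model)
  if (length(unique(conc$chrom)) > 1L) {
    abort("Markers span multiple chromosomes; delimit one chromosome at a time.")
  }
  usable <- conc[!conc$undefined, , drop = FALSE]
  co <- usable$n_discordant <= max_discordant
  if (!any(co)) {
    abort("No co-segregating marker: every marker shows recombination with the phenotype.")
  }
  runs <- rle(co)
  block_ids <- which(runs$values)
  if (length(block_ids) > 1L) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    blocks <- vapply(block_ids, function(i) {
      sprintf("%s..%s", usable$marker_id[starts[i]], usable$marker_id[ends[i]])
    }, character(1))
    abort(paste0("Ambiguous delimitation: multiple disjoint co-segregating blocks (",
                 paste(blocks, collapse = ", "), ")."))
  }
  idx <- which(co)
  left_i <- min(idx) - 1L
  right_i <- max(idx) + 1L
  open_left <- left_i < 1L
  open_right <- right_i > nrow(usable)
  start <- if (open_left) 1 else usable$pos[left_i]
  end <- if (open_right) {
    chrom_length %||% max(usable$pos)
  } else {
    usable$pos[right_i]
  }
  tibble(chrom = usable$chrom[1], start = as.numeric(start),
         end = as.numeric(end), label = "delimited",
         open_left = open_left, open_right = open_right)
}

#' Intersect two genomic intervals
#'
#' Intervals are 1-based inclusive; the intersection is
#' `[max(starts), min(ends)]` when non-empty. Length is `end - start + 1`.
#'
#' @param a,b One-row interval tibbles (columns `chrom`, `start`, `end`).
#' @return A one-row interval tibble with a `length` column, or a zero-row
#'   tibble when the intervals are disjoint.
#' @export
#' @examples
#' a <- tibble::tibble(chrom = "chr2", start = 100, end = 400)
#' b <- tibble::tibble(chrom = "chr2", start = 300, end = 600)
#' intersect_intervals(a, b)
intersect_intervals <- function(a, b) {
  if (a$chrom[1] != b$chrom[1]) {
    abort("Cannot intersect intervals on different chromosomes.")
  }
  start <- max(a$start[1], b$start[1])
  end <- min(a$end[1], b$end[1])
  if (start > end) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  length = numeric(0), label = character(0)))
  }
  tibble(chrom = a$chrom[1], start = start, end = end,
         length = end - start + 1, label = "intersection")
}
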