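#' Read a two-pool variant table
#'
#' Reads per-site allele depths for the mutant-phenotype and wild-phenotype
#' pools from either a tab-separated table (columns `chrom`, `pos`, `ref`,
#' `alt`, `mut_ref`, `mut_alt`, `wt_ref`, `wt_alt`; header required) or a
#' minimal two-sample VCF whose FORMAT includes `AD` (sample order: mutant
#' pool, then wild pool). Multiallelic and non-SNV rows are skipped with a
#' message; records are returned sorted by (chrom, pos).
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"`; guessed from the extension by default.
#' @return A variant tibble (see [snp_index_points()]).
#' @export
read_variants <- function(path, format = c("auto", "tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  out <- if (format == "vcf") read_variants_vcf(path) else read_variants_tsv(path)
  if (nrow(out) == 0L) {
    warn(sprintf("No usable variant records in '%s'.", path))
    return(out)
  }
  validate_variants(out)
  dplyr::arrange(out, .data$chrom, .data$pos)
}

variant_cols <- c("chrom", "pos", "ref", "alt",
                  "mut_ref", "mut_alt", "wt_ref", "wt_alt")

validate_variants <- function(x) {
  if (any(x$pos < 1)) abort("Variant positions must be >= 1 (1-based).")
  counts <- as.matrix(x[, c("mut_ref", "mut_alt", "wt_ref", "wt_alt")])
  if (any(counts < 0)) abort("Allele counts must be non-negative.")
  if (any(x$ref == x$alt)) abort("ref and alt must differ.")
  invisible(x)
}

drop_non_snv <- function(x) {
  snv <- nchar(x$ref) == 1L & nchar(x$alt) == 1L &
    x$ref %in% dna_bases & x$alt %in% dna_bases & !grepl(",", x$alt)
  if (any(!snv)) {
    inform(sprintf("Skipped %d multiallelic/non-SNV record(s).", sum(!snv)))
  }
  x[snv, , drop = FALSE]
}

read_variants_tsv <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(x) == 0L) return(tibble::as_tibble(stats::setNames(
    rep(list(character(0)), length(variant_cols)), variant_cols)))
  missing <- setdiff(variant_cols, names(x))
  if (length(missing)) {
    abort(paste0("Variant TSV is missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  x <- x[, variant_cols]
  count_cols <- c("pos", "mut_ref", "mut_alt", "wt_ref", "wt_alt")
  for (cc in count_cols) {
    v <- x[[cc]]
    if (any(is.na(suppressWarnings(as.numeric(v))))) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      abort(sprintf("Malformed value in column '%s' at data line %d of '%s'.",
                    cc, bad, path))
    }
    x[[cc]] <- as.integer(v)
  }
  as_tibble(drop_non_snv(x))
}

read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) return(tibble::as_tibble(stats::setNames(
    rep(list(character(0)), length(variant_cols)), variant_cols)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 3L) {
    abort("VCF must carry two samples (mutant pool, wild pool).")
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(ad) || all(is.na(ad))) {
    abort("VCF FORMAT must include AD (allele depths).")
  }
  if (any(is.na(ad))) abort("Missing AD value in VCF.")
  parse_ad <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    bad <- which(lengths(parts) < 2L)
    if (length(bad)) {
      abort(sprintf("Malformed AD field at VCF record %d.", bad[1]))
    }
    list(ref = as.integer(vapply(parts, `[[`, "", 1L)),
         alt = as.integer(vapply(parts, `[[`, "", 2L)))
  }
  mut <- parse_ad(ad[, 1L])
  wt <- parse_ad(ad[, 2L])
  out <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    mut_ref = mut$ref, mut_alt = mut$alt,
    wt_ref = wt$ref, wt_alt = wt$alt
  )
  drop_non_snv(out)
}

#' Write a variant table
#'
#' `write_variants_tsv()` writes the canonical eight-column table;
#' `write_variants_vcf()` writes a minimal VCF 4.2 with two samples
#' (`mut_pool`, `wt_pool`) carrying `AD`. Both round-trip through
#' [read_variants()].
#'
#' @param variants Variant tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  readr::write_tsv(variants[, variant_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_variants_tsv
#' @export
write_variants_vcf <- function(variants, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=bsamapr",
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "mut_pool", "wt_pool", sep = "\t")
  )
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tAD\t%d,%d\t%d,%d",
                  variants$chrom, as.integer(variants$pos), variants$ref,
                  variants$alt, variants$mut_ref, variants$mut_alt,
                  variants$wt_ref, variants$wt_alt)
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write genomic intervals as BED
#'
#' Internally intervals are 1-based inclusive; on disk BED is 0-based
#' half-open, so writing converts `start - 1` and reading converts back.
#' Overlapping intervals are preserved verbatim (no merging).
#'
#' @param intervals Interval tibble (`chrom`, `start`, `end`, optional
#'   `label`).
#' @param path File path.
#' @return `write_intervals_bed()` returns `path` invisibly;
#'   `read_intervals_bed()` returns an interval tibble.
#' @export
write_intervals_bed <- function(intervals, path) {
  label <- intervals$label %||% rep(".", nrow(intervals))
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start) - 1L,
                   as.integer(intervals$end), label)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_intervals_bed
#' @export
read_intervals_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(tibble(chrom = character(0), start = numeric(0), end = numeric(0),
                  label = character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) {
    abort(sprintf("Malformed BED line %d in '%s'.",
                  which(lengths(parts) < 3L)[1], path))
  }
  out <- tibble(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)) + 1,
    end = as.numeric(vapply(parts, `[[`, "", 3L)),
    label = vapply(parts, function(p) if (length(p) >= 4L) p[[4L]] else ".", "")
  )
  if (any(out$start < 1) || any(out$end < out$start)) {
    abort(sprintf("Invalid coordinates in '%s'.", path))
  }
  out
}

#' Read and write a recombinant marker-genotype table
#'
#' The long tab-separated dialect has columns `individual`, `phenotype`,
#' `marker_id`, `chrom`, `pos`, `genotype` (`A`/`H`/`B`, empty or `NA` for
#' missing).
#'
#' @param table Long marker table (see [simulate_marker_table()]).
#' @param path File path.
#' @return The table (read) or `path` invisibly (write).
#' @export
write_marker_table <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(
                         pos = readr::col_integer(),
                         .default = readr::col_character()))
  need <- c("individual", "phenotype", "marker_id", "chrom", "pos", "genotype")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("Marker table missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  bad <- !is.na(x$genotype) & !x$genotype %in% c("A", "H", "B")
  if (any(bad)) {
    abort(sprintf("Invalid genotype code at data line %d (expected A/H/B/NA).",
                  which(bad)[1]))
  }
  if (any(x$pos < 1)) abort("Marker positions must be >= 1.")
  dplyr::arrange(x, .data$chrom, .data$pos, .data$individual)
}

#' Read and write an accession panel table
#'
#' Tab-separated columns `id`, `te_status` (`present`/`absent`) and
#' `phenotype` (`mottled`/`nonmottled`, empty or `NA` when unrecorded).
#'
#' @param panel Panel tibble (see [simulate_panel()]).
#' @param path File path.
#' @return The panel (read) or `path` invisibly (write).
#' @export
write_panel <- function(panel, path) {
  readr::write_tsv(panel, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  need <- c("id", "te_status", "phenotype")
  missing <- setdiff(need, names(x))
  if (length(missing)) {
    abort(paste0("Panel table missing column(s): ",
                 paste(missing, collapse = ", "), "."))
  }
  bad <- !x$te_status %in% c("present", "absent")
  if (any(bad)) {
    abort(sprintf("Invalid te_status at data line %d.", which(bad)[1]))
  }
  x
}

#' Read and write reads as FASTA
#'
#' Thin wrappers over Biostrings for the plain-text FASTA used to exchange
#' per-sample read sets.
#'
#' @param reads Character vector of sequences.
#' @param path File path.
#' @param names Optional sequence names.
#' @return `write_reads_fasta()` returns `path` invisibly;
#'   `read_reads_fasta()` a character vector of sequences.
#' @export
write_reads_fasta <- function(reads, path, names = NULL) {
  seqs <- Biostrings::DNAStringSet(reads)
  names(seqs) <- names %||% sprintf("read_%06d", seq_along(reads))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_reads_fasta
#' @export
read_reads_fasta <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}

#' Write a simulation manifest
#'
#' Records the generating specification and seed as JSON so a simulated data
#' set is fully reproducible from its manifest.
#'
#' @param config A `sim_config`, `te_sim_spec` or `panel_sim_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_manifest <- function(config, path) {
  payload <- c(list(class = class(config)[1]), unclass(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null", digits = NA)
  invisible(path)
}
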