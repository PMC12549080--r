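#' Chi-square test of a two-class segregation ratio
#'
#' Tests observed counts of two phenotype classes against an expected
#' Mendelian ratio (e.g. 3:1 for a dominant monogenic trait in an F2) with
#' the uncorrected Pearson goodness-of-fit statistic on 1 df, via
#' [stats::chisq.test()]. No continuity correction is applied by default.
#'
#' @param n1,n2 Observed counts of the two classes.
#' @param ratio Length-2 numeric expected ratio, default `c(3, 1)`.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return An object of class `"seg_test"` with fields `observed`,
#'   `expected`, `ratio`, `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' segregation_chi2(257, 75)
segregation_chi2 <- function(n1, n2, ratio = c(3, 1), correct = FALSE) {
  n1 <- assert_count(n1, "n1")
  n2 <- assert_count(n2, "n2")
  if (n1 + n2 < 1L) abort("Total count must be >= 1.")
  if (length(ratio) != 2L || any(ratio <= 0)) {
    abort("`ratio` must be two positive numbers.")
  }
  p <- ratio / sum(ratio)
  obs <- c(n1, n2)
  if (correct) {
    expected <- (n1 + n2) * p
    chi2 <- sum((abs(obs - expected) - 0.5)^2 / expected)
    p_value <- pchisq(chi2, df = 1, lower.tail = FALSE)
  } else {
    ht <- suppressWarnings(chisq.test(obs, p = p))
    chi2 <- unname(ht$statistic)
    p_value <- ht$p.value
  }
  structure(
    list(observed = obs, expected = (n1 + n2) * p, ratio = ratio,
         chi2 = chi2, df = 1L, p_value = p_value, correct = correct),
    class = "seg_test"
  )
}

#' @export
print.seg_test <- function(x, ...) {
  cat(sprintf("Segregation test: %d : %d observed vs %s : %s expected\n",
              x$observed[1], x$observed[2],
              format(x$ratio[1]), format(x$ratio[2])))
  cat(sprintf("chi-square = %.2f (df = 1), P = %.2f%s\n",
              round_half_up(x$chi2, 2), round_half_up(x$p_value, 2),
              if (x$correct) " [Yates-corrected]" else ""))
  invisible(x)
}

#' @rdname segregation_chi2
#' @param x A `seg_test` object.
#' @param ... Unused.
#' @export
tidy.seg_test <- function(x, ...) {
  tibble(class = c("class1", "class2"), observed = x$observed,
         expected = x$expected)
}

#' @rdname segregation_chi2
#' @export
glance.seg_test <- function(x, ...) {
  tibble(chi2 = x$chi2, df = x$df, p_value = x$p_value)
}

#' Genotype-phenotype contingency summary for an accession panel
#'
#' Cross-tabulates TE status (absent/present) against phenotype
#' (mottled/nonmottled) over the accessions with a recorded phenotype,
#' reports row-conditional percentages (rounded half-up to 2 decimals), and
#' tests independence with the uncorrected Pearson chi-square (Yates and
#' Fisher's exact test available as options).
#'
#' @param panel Tibble with columns `te_status` (`"present"`/`"absent"`) and
#'   `phenotype` (`"mottled"`/`"nonmottled"`/`NA`), e.g. from
#'   [simulate_panel()] or [read_panel()].
#' @param correct Apply the Yates continuity correction.
#' @param exact Also compute Fisher's exact test p-value.
#' @return An object of class `"contingency_summary"`: the 2x2 `table`
#'   (rows absent/present, columns mottled/nonmottled), `percentages`
#'   (row-conditional, 2 dp), `row_totals`, `n_excluded` (missing
#'   phenotype), `chi2`, `p_value`, and `fisher_p` when `exact`.
#' @export
#' @examples
#' pan <- simulate_panel(panel_sim_spec(seed = 1))
#' contingency_summary(pan)
contingency_summary <- function(panel, correct = FALSE, exact = FALSE) {
  keep <- !is.na(panel$phenotype)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    inform(sprintf("Excluding %d accession(s) without a recorded phenotype.",
                   n_excluded))
  }
  dat <- panel[keep, , drop = FALSE]
  if (nrow(dat) == 0L) {
    abort("No accession has a recorded phenotype; cannot tabulate.")
  }
  tab <- table(factor(dat$te_status, levels = c("absent", "present")),
               factor(dat$phenotype, levels = c("mottled", "nonmottled")))
  row_totals <- rowSums(tab)
  pct <- tab
  for (i in seq_len(nrow(tab))) {
    pct[i, ] <- if (row_totals[i] > 0) {
      round_half_up(100 * tab[i, ] / row_totals[i], 2)
    } else {
      NA_real_
    }
  }
  if (any(row_totals == 0)) {
    warn("A TE-status row has zero phenotyped accessions; its percentages are undefined.")
  }
  ht <- suppressWarnings(chisq.test(tab, correct = correct))
  fisher_p <- if (exact) fisher.test(tab)$p.value else NA_real_
  structure(
    list(table = tab, percentages = pct, row_totals = row_totals,
         n_excluded = n_excluded, chi2 = unname(ht$statistic),
         p_value = ht$p.value, correct = correct, fisher_p = fisher_p),
    class = "contingency_summary"
  )
}

#' @export
print.contingency_summary <- function(x, ...) {
  cat("TE status x phenotype (counts):\n")
  print(x$table)
  cat("\nRow-conditional percentages:\n")
  print(x$percentages)
  cat(sprintf("\nchi-square = %.2f, P = %.3g%s\n",
              round_half_up(x$chi2, 2), x$p_value,
              if (x$correct) " [Yates-corrected]" else ""))
  invisible(x)
}

#' @rdname contingency_summary
#' @param x A `contingency_summary` object.
#' @param ... Unused.
#' @export
tidy.contingency_summary <- function(x, ...) {
  df <- as.data.frame(x$table)
  names(df) <- c("te_status", "phenotype", "n")
  df$row_pct <- as.vector(x$percentages)
  as_tibble(df)
}

#' @rdname contingency_summary
#' @export
glance.contingency_summary <- function(x, ...) {
  tibble(n = sum(x$table), n_excluded = x$n_excluded, chi2 = x$chi2,
         p_value = x$p_value, fisher_p = x$fisher_p)
}

#' Classify inheritance as single-gene dominant consistent
#'
#' A trait is consistent with monogenic dominant inheritance when every F1
#' individual expresses the carrier-class phenotype and the F2 segregation
#' does not reject the 3:1 ratio at level `alpha`.
#'
#' @param f1_phenotypes Character vector of F1 phenotypes.
#' @param f2_result A [segregation_chi2()] result for the F2 counts
#'   (carrier class first) against 3:1.
#' @param alpha Significance level (default 0.05).
#' @param carrier_phenotype The phenotype expected of carriers.
#' @return `"consistent"` or `"inconsistent"`.
#' @export
#' @examples
#' classify_inheritance(rep("mottled", 10), segregation_chi2(257, 75))
classify_inheritance <- function(f1_phenotypes, f2_result, alpha = 0.05,
                                 carrier_phenotype = "mottled") {
  if (length(f1_phenotypes) == 0L) abort("`f1_phenotypes` must be non-empty.")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    abort("`alpha` must be in (0, 1).")
  }
  stopifnot(inherits(f2_result, "seg_test"))
  uniform_carrier <- all(f1_phenotypes == carrier_phenotype)
  if (uniform_carrier && f2_result$p_value >= alpha) "consistent" else "inconsistent"
}
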