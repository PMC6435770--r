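# Cohort summaries and the Mann-Whitney U comparison between MMR-deficient
# and MMR-proficient clusters.

#' Mann-Whitney U test
#'
#' Two-sample rank test for a location difference. U is computed from
#' midranks. The two-tailed p-value is exact (the full permutation null
#' distribution of U) when there are no ties and `n1 * n2 <= 400`; otherwise
#' a normal approximation with tie-corrected variance and continuity
#' correction is used. The method actually applied is recorded.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_max Largest `n1 * n2` for which the exact null distribution
#'   is used (default 400).
#' @return Object of class `"mwu_test"`: `u_statistic` (oriented to `x`),
#'   `p_value`, `method` (`"exact_permutation"` or
#'   `"normal_approximation"`), `n1`, `n2`.
#' @export
mann_whitney_u <- function(x, y, exact_max = 400L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 * n2 <= exact_max) {
    # exact two-sided p from the Mann-Whitney null distribution
    if (u > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(u, n1, n2)
    }
    method <- "exact_permutation"
  } else {
    mu <- n1 * n2 / 2
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * stats::pnorm(-abs(z))
    }
    method <- "normal_approximation"
  }
  structure(list(u_statistic = u, p_value = min(p, 1), method = method,
                 n1 = n1, n2 = n2),
            class = "mwu_test")
}

#' @export
print.mwu_test <- function(x, ...) {
  cat("<mwu_test> U =", x$u_statistic, " p =", signif(x$p_value, 4),
      " (", x$method, "; n1 =", x$n1, ", n2 =", x$n2, ")\n")
  invisible(x)
}

#' Integer percent, rounding half away from zero
#' @param num,den Numerator and denominator counts.
#' @return Integer percent, or `NA` for a zero denominator.
#' @export
percent_of <- function(num, den) {
  if (den == 0) return(NA_integer_)
  as.integer(round_half_away(100 * num / den))
}

#' Summarise a joined cohort
#'
#' Computes the headline counts and fractions of the diagnostic work-up:
#' probands tested for MMR function, MMR-deficient tumors, probands subjected
#' to germline mutation screening, pathogenic mutations (overall and per
#' gene), and mean CFDR tumor count / LAD per mutated gene and cohort-wide.
#' Fractions are kept exact; `*_pct` fields round half away from zero to the
#' integer percents used for display.
#'
#' @param cfdr Data frame from [cfdr_cohort()].
#' @param lab Lab-results frame for the same probands.
#' @param n_probands Cohort size (defaults to `nrow(lab)`).
#' @return Object of class `"cohort_summary"` (a list of counts, fractions
#'   and per-gene statistics).
#' @export
summarize_cohort <- function(cfdr, lab, n_probands = nrow(lab)) {
  tested <- lab$mmr_functional != "not_done"
  deficient <- lab$mmr_functional == "deficient"
  screened <- nzchar(lab$screened_genes)
  mutated <- lab$variant_class == "pathogenic"
  genes <- mmr_genes()
  per_gene <- lapply(genes, function(g) {
    ids <- lab$proband_id[mutated & lab$mutation_gene == g]
    sub <- cfdr[cfdr$proband_id %in% ids, , drop = FALSE]
    list(n = length(ids),
         pct_of_mutations = percent_of(length(ids), sum(mutated)),
         mean_tumor_count = if (nrow(sub) > 0L) mean(sub$tumor_count)
                            else NA_real_,
         mean_lad = if (nrow(sub) > 0L) mean(sub$lad) else NA_real_)
  })
  names(per_gene) <- genes
  structure(list(
    n_probands = n_probands,
    n_mmr_tested = sum(tested),
    n_mmr_deficient = sum(deficient),
    mmr_deficient_frac = if (sum(tested) > 0) sum(deficient) / sum(tested)
                         else NA_real_,
    mmr_deficient_pct = percent_of(sum(deficient), sum(tested)),
    n_screened = sum(screened),
    n_mutation = sum(mutated),
    mutation_of_screened_frac = if (sum(screened) > 0)
      sum(mutated) / sum(screened) else NA_real_,
    mutation_of_screened_pct = percent_of(sum(mutated), sum(screened)),
    mutation_of_cohort_frac = if (n_probands > 0)
      sum(mutated) / n_probands else NA_real_,
    mutation_of_cohort_pct = percent_of(sum(mutated), n_probands),
    per_gene = per_gene,
    mean_tumor_count = if (nrow(cfdr) > 0L) mean(cfdr$tumor_count)
                       else NA_real_,
    mean_lad = if (nrow(cfdr) > 0L) mean(cfdr$lad) else NA_real_
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>", x$n_probands, "probands\n")
  cat("  MMR tested:", x$n_mmr_tested, "| deficient:", x$n_mmr_deficient,
      paste0("(", x$mmr_deficient_pct, "%)"), "\n")
  cat("  screened:", x$n_screened, "| pathogenic mutation:", x$n_mutation,
      paste0("(", x$mutation_of_screened_pct, "% of screened, "),
      paste0(x$mutation_of_cohort_pct, "% of cohort)"), "\n")
  pg <- vapply(x$per_gene, function(g) g$n, numeric(1))
  cat("  per gene:", paste(names(pg), pg, sep = "=", collapse = ", "), "\n")
  cat("  mean CFDR tumors:", round(x$mean_tumor_count, 2),
      "| mean LAD:", round(x$mean_lad, 1), "\n")
  invisible(x)
}

#' Compare CFDR tumor burden and LAD by MMR status
#'
#' Mann-Whitney U tests of CFDR tumor count and LAD between probands with
#' MMR-deficient versus MMR-proficient tumors, with the direction of the
#' median difference.
#'
#' @param cfdr Data frame from [cfdr_cohort()].
#' @param lab Lab-results frame.
#' @return List with elements `tumor_count` and `lad`, each holding the
#'   `"mwu_test"`, the group medians, and `direction`
#'   (`"deficient_higher"`, `"deficient_lower"` or `"equal"`).
#' @export
compare_by_mmr_status <- function(cfdr, lab) {
  m <- merge(cfdr, lab[c("proband_id", "mmr_functional")], by = "proband_id")
  d <- m[m$mmr_functional == "deficient", , drop = FALSE]
  p <- m[m$mmr_functional == "proficient", , drop = FALSE]
  if (nrow(d) == 0L || nrow(p) == 0L) {
    stop("both MMR status groups must be non-empty", call. = FALSE)
  }
  one <- function(var) {
    md <- stats::median(d[[var]]); mp <- stats::median(p[[var]])
    list(test = mann_whitney_u(d[[var]], p[[var]]),
         median_deficient = md, median_proficient = mp,
         direction = if (md > mp) "deficient_higher"
                     else if (md < mp) "deficient_lower" else "equal")
  }
  list(tumor_count = one("tumor_count"), lad = one("lad"),
       n_deficient = nrow(d), n_proficient = nrow(p))
}

#' Cutoff polyline for the CFDR-versus-LAD scatter
#'
#' The dashed boundary separating direct-panel eligibility in the report
#' figures: LAD 40 at one tumor, 50 at two, 60 at three or more.
#'
#' @return Data frame with columns `tumor_count`, `lad_cutoff`.
#' @export
cutoff_polyline <- function() {
  data.frame(tumor_count = c(1L, 2L, 3L), lad_cutoff = c(40L, 50L, 60L))
}
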