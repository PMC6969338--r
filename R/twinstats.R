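#' Build a twin-pair table from a cohort
#'
#' Reshapes per-subject phenotype values into one row per pair with
#' `value_twin1` / `value_twin2` ordered by birth order (no double entry).
#' Incomplete pairs are dropped.
#'
#' @param cohort a `twin_cohort` data.frame.
#' @param value numeric vector of phenotype values aligned with the cohort
#'   rows, or the name of a cohort column.
#' @return data.frame of class `twin_pairs` with columns `pair_id`,
#'   `zygosity`, `value_twin1`, `value_twin2`.
#' @export
twin_pairs <- function(cohort, value) {
  if (is.character(value) && length(value) == 1L)
    value <- cohort[[value]]
  stopifnot(length(value) == nrow(cohort))
  keep <- cohort$complete_pair %||% rep(TRUE, nrow(cohort))
  df <- data.frame(pair_id = cohort$pair_id,
                   zygosity = cohort$zygosity,
                   birth_order = cohort$birth_order,
                   value = value,
                   stringsAsFactors = FALSE)[keep, , drop = FALSE]
  df <- df[order(df$pair_id, df$birth_order), ]
  first <- df[!duplicated(df$pair_id), ]
  second <- df[duplicated(df$pair_id), ]
  out <- data.frame(pair_id = first$pair_id,
                    zygosity = first$zygosity,
                    value_twin1 = first$value,
                    value_twin2 = second$value[match(first$pair_id,
                                                     second$pair_id)],
                    stringsAsFactors = FALSE)
  class(out) <- c("twin_pairs", "data.frame")
  out
}

#' Within-twin Pearson correlation by zygosity
#'
#' Pearson correlation between co-twins' phenotype values over the complete
#' pairs of one zygosity group, with the usual t-based two-sided p-value
#' (n - 2 degrees of freedom).
#'
#' @param pairs a [twin_pairs()] table.
#' @param zygosity `"MZ"` or `"DZ"`.
#' @return list with `r`, `n` (complete pairs used) and `p`.
#' @export
within_twin_correlation <- function(pairs, zygosity = c("MZ", "DZ")) {
  zygosity <- match.arg(zygosity)
  sub <- pairs[pairs$zygosity == zygosity, , drop = FALSE]
  ok <- stats::complete.cases(sub$value_twin1, sub$value_twin2)
  sub <- sub[ok, , drop = FALSE]
  if (nrow(sub) < 3L)
    stop("need at least 3 complete ", zygosity, " pairs", call. = FALSE)
  ct <- stats::cor.test(sub$value_twin1, sub$value_twin2)
  list(r = unname(ct$estimate), n = nrow(sub), p = ct$p.value)
}

#' Compare two independent correlations (Fisher r-to-z)
#'
#' Two-sample z-test for the difference of two independent Pearson
#' correlations via the variance-stabilizing transform:
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided normal p-value. Used to test whether MZ within-twin
#' correlations exceed DZ correlations.
#'
#' @param r1,r2 correlations, strictly inside (-1, 1).
#' @param n1,n2 sample sizes (complete pairs), each > 3.
#' @return list of class `fisher_z` with `z`, `p` and the echoed inputs.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop("|r| must be < 1 for the r-to-z transform", call. = FALSE)
  if (n1 <= 3 || n2 <= 3)
    stop("need n > 3 in both groups", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  structure(list(z = z, p = 2 * stats::pnorm(-abs(z)),
                 r1 = r1, n1 = n1, r2 = r2, n2 = n2),
            class = "fisher_z")
}

#' @export
print.fisher_z <- function(x, ...) {
  cat(sprintf("Fisher r-to-z: r1 = %.3f (n = %d) vs r2 = %.3f (n = %d)\n",
              x$r1, x$n1, x$r2, x$n2))
  cat(sprintf("  Z = %.3f, two-sided p = %.4g\n", x$z, x$p))
  invisible(x)
}

#' Bonferroni-corrected correlations of distress measures with an outcome
#'
#' Pearson correlation of each distress column with the outcome, flagged
#' significant iff p < alpha / m_tests (default family-wise level 0.05 over
#' the six distress estimates: tension and excitement at three timepoints).
#'
#' @param distress data.frame or matrix of distress measures (columns are
#'   the tested family).
#' @param outcome numeric outcome vector (e.g. number of completed scans).
#' @param m_tests size of the test family; defaults to `ncol(distress)`.
#' @param alpha family-wise error level.
#' @return data.frame with one row per measure: `r`, `n`, `p`,
#'   `significant`; the adjusted level is in attribute `"alpha_adjusted"`.
#' @export
bonferroni_correlations <- function(distress, outcome,
                                    m_tests = ncol(distress),
                                    alpha = 0.05) {
  stopifnot(m_tests >= 1)
  adj <- alpha / m_tests
  rows <- lapply(colnames(distress), function(nm) {
    x <- distress[[nm]]
    ok <- stats::complete.cases(x, outcome)
    ct <- stats::cor.test(x[ok], outcome[ok])
    data.frame(measure = nm, r = unname(ct$estimate), n = sum(ok),
               p = ct$p.value, significant = ct$p.value < adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha_adjusted") <- adj
  out
}

#' One-way repeated-measures ANOVA over timepoints
#'
#' Within-subject F-test for a change over k timepoints (listwise-complete
#' subjects), with df (k - 1, (k - 1)(n - 1)), plus Bonferroni-corrected
#' pairwise follow-up comparisons. Degenerate data with (near-)zero error
#' variance raise an error rather than an unbounded F.
#'
#' @param values numeric matrix, subjects in rows, timepoints in columns.
#' @return list with `F`, `df_effect`, `df_error`, `p`, `means`, and
#'   `pairwise` (Bonferroni-adjusted paired-t p-value matrix).
#' @export
repeated_measures_f <- function(values) {
  m <- as.matrix(values)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 3L) stop("need at least 3 complete subjects", call. = FALSE)
  if (k < 2L) stop("need at least 2 timepoints", call. = FALSE)
  long <- data.frame(
    y = as.vector(m),
    time = factor(rep(seq_len(k), each = n)),
    subject = factor(rep(seq_len(n), times = k))
  )
  fit <- stats::aov(y ~ time + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ms_err <- tab["Residuals", "Mean Sq"]
  ms_time <- tab["time", "Mean Sq"]
  tiny <- max(stats::var(as.vector(m)), 1) * 1e-12
  if (!is.finite(ms_err) || ms_err <= tiny) {
    # no within-subject error variance: F is 0/0 when the timepoints are
    # identical, unbounded when they differ by a constant
    if (is.finite(ms_time) && ms_time > tiny)
      stop("zero within-subject error variance with a nonzero timepoint ",
           "effect: F unbounded", call. = FALSE)
    return(list(F = 0, df_effect = k - 1, df_error = (k - 1) * (n - 1),
                p = 1, means = colMeans(m), pairwise = NULL))
  }
  pw <- stats::pairwise.t.test(long$y, long$time, paired = TRUE,
                               p.adjust.method = "bonferroni")
  list(F = tab["time", "F value"],
       df_effect = tab["time", "Df"],
       df_error = tab["Residuals", "Df"],
       p = tab["time", "Pr(>F)"],
       means = colMeans(m),
       pairwise = pw$p.value)
}
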