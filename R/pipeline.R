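#' Run the full quantity/quality analysis pipeline
#'
#' Simulates (or accepts) a twin cohort, computes per-run motion summaries
#' and subject-level motion means, applies quality control, and produces
#' the three standard result tables: a per-run motion table (all vs
#' included participants), a quantity/quality/attrition summary, and
#' per-phenotype twin statistics (within-twin correlations by zygosity,
#' MZ-vs-DZ Fisher z, and ACE variance decompositions). Head-motion
#' phenotypes (session-mean FD and AD) are analysed in three nested motion
#' strata - all scanned participants, moderate motion, and minimal motion -
#' with stratum membership recomputed from the subject motion means and
#' exclusion applied before pairing and model fitting.
#'
#' @param config a [cohort_config()].
#' @param seed root seed; the whole report is deterministic given
#'   `(config, seed)`.
#' @param cohort optionally, an existing `twin_cohort_sim` (overrides
#'   `config`/`seed` for generation).
#' @param thresholds a [qc_thresholds()].
#' @param stringency,rs_rule quality-control settings, see [scan_quality()].
#' @param ci compute profile-likelihood CIs for the ACE fits (slower).
#' @return list of class `pipeline_report` with `tables` (named
#'   data.frames), `fits` (the `ace_fit` objects), `qc`, `summaries` and a
#'   `provenance` block.
#' @export
run_pipeline <- function(config = cohort_config(), seed = 1,
                         cohort = NULL,
                         thresholds = qc_thresholds(),
                         stringency = "stringent",
                         rs_rule = "stringent",
                         ci = FALSE) {
  if (is.null(cohort)) cohort <- generate_cohort(config, seed)
  records <- cohort$records
  config <- cohort$config

  summaries <- do.call(rbind, lapply(cohort$traces, summarize_run))
  rownames(summaries) <- NULL
  qc <- cohort_qc(records, summaries, config$protocol, thresholds,
                  stringency, rs_rule)

  motion_table <- .motion_table(summaries, config$protocol, thresholds,
                                rs_rule)
  qc$quality_fraction <- qc$included_fraction

  phen <- list(mean_fd = qc$mean_fd, mean_ad = qc$mean_ad,
               quantity = qc$n_completed,
               quality_fraction = qc$quality_fraction)

  strata <- list(all = rep(TRUE, nrow(qc)),
                 moderate = !is.na(qc$stratum) &
                   qc$stratum %in% c("minimal", "moderate"),
                 minimal = !is.na(qc$stratum) & qc$stratum == "minimal")

  twin_rows <- list(); ace_rows <- list(); fits <- list()
  jobs <- rbind(expand.grid(phenotype = c("mean_fd", "mean_ad"),
                            stratum = c("all", "moderate", "minimal"),
                            stringsAsFactors = FALSE),
                data.frame(phenotype = c("quantity", "quality_fraction"),
                           stratum = "all", stringsAsFactors = FALSE))
  for (j in seq_len(nrow(jobs))) {
    ph <- jobs$phenotype[j]; strat <- jobs$stratum[j]
    val <- phen[[ph]]
    val[!strata[[strat]]] <- NA
    pairs <- twin_pairs(records, val)
    pairs <- pairs[stats::complete.cases(pairs$value_twin1,
                                         pairs$value_twin2), ]
    key <- paste(ph, strat, sep = ".")
    cmz <- tryCatch(within_twin_correlation(pairs, "MZ"),
                    error = function(e) NULL)
    cdz <- tryCatch(within_twin_correlation(pairs, "DZ"),
                    error = function(e) NULL)
    fz <- if (!is.null(cmz) && !is.null(cdz) &&
              abs(cmz$r) < 1 && abs(cdz$r) < 1)
      fisher_z_compare(cmz$r, cmz$n, cdz$r, cdz$n) else NULL
    twin_rows[[key]] <- data.frame(
      phenotype = ph, stratum = strat,
      r_mz = cmz$r %||% NA_real_, n_mz = cmz$n %||% 0L,
      p_mz = cmz$p %||% NA_real_,
      r_dz = cdz$r %||% NA_real_, n_dz = cdz$n %||% 0L,
      p_dz = cdz$p %||% NA_real_,
      fisher_z = fz$z %||% NA_real_, fisher_p = fz$p %||% NA_real_,
      stringsAsFactors = FALSE)
    fit <- tryCatch(fit_ace(pairs), error = function(e) NULL)
    fits[[key]] <- fit
    cint <- if (ci && !is.null(fit)) stats::confint(fit) else NULL
    ace_rows[[key]] <- data.frame(
      phenotype = ph, stratum = strat,
      a2 = fit$a2 %||% NA_real_, c2 = fit$c2 %||% NA_real_,
      e2 = fit$e2 %||% NA_real_,
      a2_lo = if (!is.null(cint)) cint["a2", 1] else NA_real_,
      a2_hi = if (!is.null(cint)) cint["a2", 2] else NA_real_,
      c2_lo = if (!is.null(cint)) cint["c2", 1] else NA_real_,
      c2_hi = if (!is.null(cint)) cint["c2", 2] else NA_real_,
      e2_lo = if (!is.null(cint)) cint["e2", 1] else NA_real_,
      e2_hi = if (!is.null(cint)) cint["e2", 2] else NA_real_,
      n_mz = fit$n_mz %||% 0L, n_dz = fit$n_dz %||% 0L,
      loglik = fit$loglik %||% NA_real_,
      converged = fit$converged %||% FALSE,
      stringsAsFactors = FALSE)
  }

  attrition <- .attrition_table(records, qc, config$protocol)
  reliability <- .reliability(summaries, records, config$protocol)

  tables <- list(motion = motion_table,
                 qc = qc,
                 twin = do.call(rbind, twin_rows),
                 ace = do.call(rbind, ace_rows),
                 attrition = attrition)
  rownames(tables$twin) <- rownames(tables$ace) <- NULL

  structure(list(tables = tables,
                 fits = fits,
                 qc = qc,
                 summaries = summaries,
                 reliability = reliability,
                 provenance = list(seed = cohort$seed,
                                   config_hash = .config_hash(config),
                                   n_pairs = config$n_pairs,
                                   package_version =
                                     as.character(utils::packageVersion("twinmotion")))),
            class = "pipeline_report")
}

# Table-1-like per-run motion summary, all vs included participants.
.motion_table <- function(summaries, protocol, thresholds, rs_rule) {
  rows <- list()
  for (lab in fmri_runs(protocol)) {
    s <- summaries[summaries$run_label == lab, , drop = FALSE]
    if (!nrow(s)) next
    mod <- protocol$runs$modality[match(lab, protocol$runs$run_label)]
    inc <- if (mod == "task_fmri") classify_task_run(s, thresholds)
           else classify_rs_run(s, rs_rule, thresholds)
    for (grp in c("all", "included")) {
      g <- if (grp == "all") s else s[inc, , drop = FALSE]
      if (!nrow(g)) next
      rows[[paste(lab, grp)]] <- data.frame(
        run_label = lab, group = grp, n = nrow(g),
        mean_fd = mean(g$mean_fd), sd_fd = stats::sd(g$mean_fd),
        mean_ad = mean(g$mean_ad), sd_ad = stats::sd(g$mean_ad),
        mean_ad_x = mean(g$mean_ad_x), mean_ad_y = mean(g$mean_ad_y),
        mean_ad_z = mean(g$mean_ad_z),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Window-inclusion counts by sex among children who completed the protocol.
.attrition_table <- function(records, qc, protocol) {
  full <- qc$n_completed == protocol$quantity_denominator
  rows <- list()
  for (w in c(30, 45, 60)) {
    col <- paste0("window_", w)
    for (sx in unique(records$sex)) {
      idx <- full & records$sex == sx
      rows[[paste(w, sx)]] <- data.frame(
        window_minutes = w, sex = sx, n_complete_protocol = sum(idx),
        n_included = sum(qc[[col]][idx]),
        pct_included = if (sum(idx)) 100 * mean(qc[[col]][idx]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$window_minutes, out$sex), ]
}

# Cross-run reliability (Cronbach's alpha) of mean FD and mean AD.
.reliability <- function(summaries, records, protocol) {
  labs <- fmri_runs(protocol)
  mk <- function(col) {
    m <- sapply(labs, function(l) {
      s <- summaries[summaries$run_label == l, ]
      s[[col]][match(records$subject_id, s$subject_id)]
    })
    tryCatch(cronbach_alpha(m), error = function(e) NA_real_)
  }
  c(alpha_mean_fd = mk("mean_fd"), alpha_mean_ad = mk("mean_ad"))
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config[setdiff(names(config), "protocol")]), f)
  unname(tools::md5sum(f))
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Twin MRI quantity/quality pipeline report\n")
  cat("  seed:", x$provenance$seed,
      " pairs:", x$provenance$n_pairs,
      " config:", substr(x$provenance$config_hash, 1, 8), "\n")
  cat(sprintf("  reliability: alpha(FD) = %.2f, alpha(AD) = %.2f\n",
              x$reliability["alpha_mean_fd"],
              x$reliability["alpha_mean_ad"]))
  cat("\nTwin correlations and Fisher z:\n")
  print(x$tables$twin, digits = 3, row.names = FALSE)
  cat("\nACE decompositions:\n")
  print(x$tables$ace, digits = 3, row.names = FALSE)
  invisible(x)
}
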