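#' Quality-control thresholds
#'
#' All thresholds are applied as strict inequalities, exactly as usually
#' printed: task runs are included with maximum per-axis displacement
#' < 3 mm (one voxel); resting-state runs with < 20% of frames flagged at
#' the > 0.3 mm (stringent) or > 0.5 mm (lenient) FD threshold; subjects are
#' stratified into "moderate" (mean FD < 1 mm and mean AD < 3 mm) and
#' "minimal" (mean FD < 0.3 mm and mean AD < 1 mm) motion.
#'
#' @param task_max_ad maximum per-axis displacement for task runs, mm.
#' @param rs_fd_stringent,rs_fd_lenient FD outlier thresholds, mm.
#' @param rs_max_flagged_fraction maximum flagged-frame fraction for RS.
#' @param moderate_mean_fd,moderate_mean_ad moderate-motion bounds, mm.
#' @param minimal_mean_fd,minimal_mean_ad minimal-motion bounds, mm.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(task_max_ad = 3.0,
                          rs_fd_stringent = 0.3,
                          rs_fd_lenient = 0.5,
                          rs_max_flagged_fraction = 0.20,
                          moderate_mean_fd = 1.0,
                          moderate_mean_ad = 3.0,
                          minimal_mean_fd = 0.3,
                          minimal_mean_ad = 1.0) {
  thr <- list(task_max_ad = task_max_ad,
              rs_fd_stringent = rs_fd_stringent,
              rs_fd_lenient = rs_fd_lenient,
              rs_max_flagged_fraction = rs_max_flagged_fraction,
              moderate_mean_fd = moderate_mean_fd,
              moderate_mean_ad = moderate_mean_ad,
              minimal_mean_fd = minimal_mean_fd,
              minimal_mean_ad = minimal_mean_ad)
  if (any(unlist(thr) <= 0)) stop("thresholds must be positive", call. = FALSE)
  if (minimal_mean_fd >= moderate_mean_fd ||
      minimal_mean_ad >= moderate_mean_ad)
    stop("minimal-motion bounds must lie below moderate bounds",
         call. = FALSE)
  if (rs_fd_stringent >= rs_fd_lenient)
    stop("stringent FD threshold must lie below the lenient one",
         call. = FALSE)
  structure(thr, class = "qc_thresholds")
}

#' Include/exclude a completed task-fMRI run
#'
#' A task run is of sufficient quality iff its maximum per-axis displacement
#' is strictly below the task threshold (default < 3 mm in all directions).
#'
#' @param summary one-row run summary from [summarize_run()].
#' @param thresholds a [qc_thresholds()].
#' @return logical.
#' @export
classify_task_run <- function(summary, thresholds = qc_thresholds()) {
  summary$max_abs_per_axis < thresholds$task_max_ad
}

#' Include/exclude a completed resting-state run
#'
#' Under `"stringent"` (`"lenient"`) the run is included iff strictly fewer
#' than 20% of its FD frames exceed 0.3 mm (0.5 mm). `"ad3"` applies the
#' task-run maximum-displacement rule instead.
#'
#' @inheritParams classify_task_run
#' @param stringency one of `"stringent"`, `"lenient"`, `"ad3"`.
#' @return logical.
#' @export
classify_rs_run <- function(summary,
                            stringency = c("stringent", "lenient", "ad3"),
                            thresholds = qc_thresholds()) {
  stringency <- match.arg(stringency)
  switch(stringency,
         stringent = summary$frac_flagged_03 <
           thresholds$rs_max_flagged_fraction,
         lenient = summary$frac_flagged_05 <
           thresholds$rs_max_flagged_fraction,
         ad3 = classify_task_run(summary, thresholds))
}

.rating_levels <- c("Excellent", "Good", "Doubtful", "Failed")

#' Include/exclude a manually rated scan (T1 or DTI)
#'
#' Stringent quality control includes `Excellent` and `Good` scans; lenient
#' additionally includes `Doubtful`. `Failed` is never included.
#'
#' @param rating character vector of ratings on the 4-level scale.
#' @param stringency `"stringent"` or `"lenient"`.
#' @return logical vector.
#' @export
classify_rated_scan <- function(rating,
                                stringency = c("stringent", "lenient")) {
  stringency <- match.arg(stringency)
  bad <- setdiff(unique(rating[!is.na(rating)]), .rating_levels)
  if (length(bad))
    stop("unknown rating label: ", paste(bad, collapse = ", "),
         call. = FALSE)
  ok <- if (stringency == "stringent") c("Excellent", "Good")
        else c("Excellent", "Good", "Doubtful")
  !is.na(rating) & rating %in% ok
}

.completed_cols <- function(record, protocol) {
  cols <- paste0("completed_", protocol$runs$run_label)
  miss <- setdiff(cols, names(record))
  if (length(miss))
    stop("missing completion flags: ", paste(miss, collapse = ", "),
         call. = FALSE)
  extra <- setdiff(grep("^completed_", names(record), value = TRUE), cols)
  if (length(extra))
    stop("completion flags for runs not in the protocol: ",
         paste(extra, collapse = ", "), call. = FALSE)
  cols
}

#' Scan quantity: number of completed runs
#'
#' Counts the protocol runs a child completed (0-9 for the default
#' protocol). A never-scanned child scores 0. Completing a run says nothing
#' about whether its data are usable; see [scan_quality()].
#'
#' @param record one or more cohort rows with `completed_<run>` flags.
#' @param protocol an [mri_protocol()].
#' @return integer vector.
#' @export
scan_quantity <- function(record, protocol = default_protocol()) {
  cols <- .completed_cols(record, protocol)
  flags <- as.matrix(record[, cols, drop = FALSE])
  flags[is.na(flags)] <- FALSE
  as.integer(rowSums(flags))
}

#' Scan quality: included quality units and included fraction
#'
#' Counts the quality units (task runs, T1, the merged DTI unit, RS) that
#' were completed and pass their inclusion rule, and the fraction relative
#' to the completed units. Runs never completed contribute to neither the
#' numerator nor the denominator; the fraction is `NA` for children with no
#' completed quality unit. The DTI unit counts as completed iff every DTI
#' run was completed.
#'
#' @param record one cohort row with completion flags and `rating_t1`,
#'   `rating_dti` columns.
#' @param summaries run summaries for this subject's completed fMRI runs.
#' @param protocol an [mri_protocol()].
#' @param thresholds a [qc_thresholds()].
#' @param stringency rating stringency for T1/DTI, `"stringent"`/`"lenient"`.
#' @param rs_rule resting-state rule, see [classify_rs_run()].
#' @return list with `n_included`, `n_completed_units`, `included_fraction`,
#'   and `unit_included` / `unit_completed` named logical vectors.
#' @export
scan_quality <- function(record, summaries,
                         protocol = default_protocol(),
                         thresholds = qc_thresholds(),
                         stringency = c("stringent", "lenient"),
                         rs_rule = c("stringent", "lenient", "ad3")) {
  stringency <- match.arg(stringency)
  rs_rule <- match.arg(rs_rule)
  units <- .quality_units(protocol$runs)
  runs <- protocol$runs
  completed <- vapply(units, function(labs) {
    all(vapply(labs, function(l)
      isTRUE(record[[paste0("completed_", l)]]), logical(1)))
  }, logical(1))
  included <- logical(length(units))
  names(included) <- names(units)
  for (u in names(units)) {
    if (!completed[[u]]) next
    labs <- units[[u]]
    mod <- runs$modality[match(labs[1], runs$run_label)]
    included[[u]] <- switch(
      mod,
      task_fmri = {
        s <- summaries[summaries$run_label == labs[1], , drop = FALSE]
        nrow(s) == 1L && classify_task_run(s, thresholds)
      },
      rs_fmri = {
        s <- summaries[summaries$run_label == labs[1], , drop = FALSE]
        nrow(s) == 1L && classify_rs_run(s, rs_rule, thresholds)
      },
      t1 = classify_rated_scan(record[["rating_t1"]], stringency),
      dti = classify_rated_scan(record[["rating_dti"]], stringency)
    )
  }
  n_completed <- sum(completed)
  list(n_included = sum(included),
       n_completed_units = n_completed,
       included_fraction = if (n_completed > 0) sum(included) / n_completed
                           else NA_real_,
       unit_included = included,
       unit_completed = completed)
}

#' Motion stratum of a subject
#'
#' Nested strata by session-mean motion: `minimal` (mean FD < 0.3 mm and
#' mean AD < 1 mm), else `moderate` (mean FD < 1 mm and mean AD < 3 mm),
#' else `excessive`. Strata nest: minimal subjects satisfy the moderate
#' bounds too.
#'
#' @param mean_fd,mean_ad subject-level mean motion in mm (vectorized).
#' @param thresholds a [qc_thresholds()].
#' @return factor with levels `minimal`, `moderate`, `excessive`.
#' @export
motion_stratum <- function(mean_fd, mean_ad, thresholds = qc_thresholds()) {
  out <- ifelse(
    mean_fd < thresholds$minimal_mean_fd &
      mean_ad < thresholds$minimal_mean_ad, "minimal",
    ifelse(mean_fd < thresholds$moderate_mean_fd &
             mean_ad < thresholds$moderate_mean_ad, "moderate", "excessive"))
  factor(out, levels = c("minimal", "moderate", "excessive"))
}

# Quality units making up each inclusion time window of the default-style
# protocol: first 30 min = first four task runs; 45 min = all task runs +
# T1; 60 min = the full set of quality units.
.window_units <- function(protocol, window_minutes) {
  units <- names(.quality_units(protocol$runs))
  task <- protocol$runs$run_label[protocol$runs$modality == "task_fmri"]
  switch(as.character(window_minutes),
         "30" = utils::head(task, 4L),
         "45" = c(task, "t1"),
         "60" = units,
         stop("unsupported window: ", window_minutes, call. = FALSE))
}

#' Session-length inclusion windows
#'
#' Whether a child has sufficient-quality data on every quality unit
#' acquired within the first 30, 45 or 60 minutes of the session. The
#' windows nest, so 60-minute inclusion implies 45- and 30-minute
#' inclusion.
#'
#' @inheritParams scan_quality
#' @param window_minutes one of 30, 45, 60.
#' @return logical.
#' @export
time_window_inclusion <- function(record, summaries,
                                  window_minutes,
                                  protocol = default_protocol(),
                                  thresholds = qc_thresholds(),
                                  stringency = "stringent",
                                  rs_rule = "stringent") {
  q <- scan_quality(record, summaries, protocol, thresholds,
                    stringency, rs_rule)
  w <- .window_units(protocol, window_minutes)
  all(q$unit_completed[w] & q$unit_included[w])
}

#' Per-subject QC table for a cohort
#'
#' Applies the full quality-control cascade to every subject: completed-run
#' count, included quality units, included fraction, session-mean motion,
#' motion stratum, and the three time-window inclusion flags.
#'
#' @param cohort a `twin_cohort` data.frame.
#' @param summaries data.frame of run summaries for all subjects/runs.
#' @inheritParams scan_quality
#' @return data.frame with one row per subject.
#' @export
cohort_qc <- function(cohort, summaries,
                      protocol = default_protocol(),
                      thresholds = qc_thresholds(),
                      stringency = "stringent",
                      rs_rule = "stringent") {
  rows <- lapply(seq_len(nrow(cohort)), function(i) {
    rec <- cohort[i, , drop = FALSE]
    sm <- summaries[summaries$subject_id == rec$subject_id, , drop = FALSE]
    q <- scan_quality(rec, sm, protocol, thresholds, stringency, rs_rule)
    keep <- sm$run_label %in% fmri_runs(protocol)
    mfd <- if (any(keep)) mean(sm$mean_fd[keep]) else NA_real_
    mad_ <- if (any(keep)) mean(sm$mean_ad[keep]) else NA_real_
    data.frame(
      subject_id = rec$subject_id,
      n_completed = scan_quantity(rec, protocol),
      n_included = q$n_included,
      included_fraction = q$included_fraction,
      mean_fd = mfd,
      mean_ad = mad_,
      window_30 = all(q$unit_completed[.window_units(protocol, 30)] &
                        q$unit_included[.window_units(protocol, 30)]),
      window_45 = all(q$unit_completed[.window_units(protocol, 45)] &
                        q$unit_included[.window_units(protocol, 45)]),
      window_60 = all(q$unit_completed[.window_units(protocol, 60)] &
                        q$unit_included[.window_units(protocol, 60)]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$stratum <- motion_stratum(out$mean_fd, out$mean_ad, thresholds)
  out
}
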