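#' Framewise displacement
#'
#' Summarizes volume-to-volume head movement as the sum of the absolute
#' backward differences of the three translations plus the three rotations
#' converted to mm of arc on a sphere of radius `head_radius` (the standard
#' 50 mm small-angle convention). The series has length `n_volumes - 1`: no
#' displacement is defined for the first volume, and the run's mean FD is
#' the mean of these `N - 1` values.
#'
#' @param trace a [motion_trace()].
#' @param head_radius sphere radius in mm used to convert rotations.
#' @return numeric vector of length `n_volumes - 1`, in mm.
#' @export
framewise_displacement <- function(trace, head_radius = 50) {
  stopifnot(inherits(trace, "motion_trace"))
  if (trace$n_volumes < 2L)
    stop("framewise displacement needs at least 2 volumes", call. = FALSE)
  rowSums(abs(diff(trace$translations))) +
    head_radius * rowSums(abs(diff(trace$rotations)))
}

#' Per-axis absolute displacement
#'
#' Distance of each volume's head position from a reference volume,
#' separately in x, y and z. Only translations enter: the field reports AD
#' per axis in mm, so rotations contribute to framewise displacement only
#' (a deliberate simplification, documented in the methods vignette). The
#' default reference is the middle volume, index `floor(N / 2)` in 0-based
#' terms.
#'
#' @param trace a [motion_trace()].
#' @param ref_index 1-based reference volume index; default middle volume.
#' @return N x 3 matrix of absolute displacements in mm; the reference row
#'   is zero.
#' @export
absolute_displacement <- function(trace, ref_index = NULL) {
  stopifnot(inherits(trace, "motion_trace"))
  n <- trace$n_volumes
  if (is.null(ref_index)) ref_index <- floor(n / 2) + 1L
  if (ref_index < 1L || ref_index > n)
    stop("ref_index out of range [1, ", n, "]", call. = FALSE)
  ad <- abs(sweep(trace$translations, 2L, trace$translations[ref_index, ]))
  colnames(ad) <- c("x", "y", "z")
  ad
}

#' Flag high-motion volumes
#'
#' Flags framewise-displacement values strictly above `threshold` (outlier
#' volumes, e.g. >0.3 mm stringent or >0.5 mm lenient). The flagged fraction
#' is computed over the FD frames (`N - 1` values), not the N volumes.
#'
#' @param fd_series framewise-displacement series from
#'   [framewise_displacement()].
#' @param threshold positive threshold in mm.
#' @return list with `flags` (logical vector) and `fraction` (in \[0, 1\]).
#' @export
flag_outliers <- function(fd_series, threshold) {
  if (!length(fd_series))
    stop("empty framewise-displacement series", call. = FALSE)
  stopifnot(threshold > 0)
  flags <- fd_series > threshold
  list(flags = flags, fraction = mean(flags))
}

#' Summarize one run's motion
#'
#' Computes mean FD, per-axis and overall mean absolute displacement, the
#' maximum per-axis displacement, and the fractions of frames flagged at the
#' 0.3 mm and 0.5 mm FD thresholds. `mean_ad` is the mean of the three axis
#' means, matching how per-run motion tables report "mean X, Y, Z".
#'
#' @inheritParams framewise_displacement
#' @inheritParams absolute_displacement
#' @return one-row data.frame (a run motion summary).
#' @export
summarize_run <- function(trace, head_radius = 50, ref_index = NULL) {
  fd <- framewise_displacement(trace, head_radius = head_radius)
  ad <- absolute_displacement(trace, ref_index = ref_index)
  ax <- colMeans(ad)
  data.frame(
    subject_id = trace$subject_id,
    run_label = trace$run_label,
    n_volumes = trace$n_volumes,
    mean_fd = mean(fd),
    mean_ad_x = ax[["x"]], mean_ad_y = ax[["y"]], mean_ad_z = ax[["z"]],
    mean_ad = mean(ax),
    max_abs_per_axis = max(ad),
    frac_flagged_03 = mean(fd > 0.3),
    frac_flagged_05 = mean(fd > 0.5),
    stringsAsFactors = FALSE
  )
}

#' Subject-level mean motion over fMRI runs
#'
#' Unweighted mean of the per-run mean FD and mean AD over the subject's
#' available fMRI runs (task and resting state). Absent runs are excluded,
#' never imputed as zero.
#'
#' @param summaries data.frame of run summaries ([summarize_run()] rows) for
#'   one subject.
#' @param protocol an [mri_protocol()]; only its fMRI runs are averaged.
#' @return one-row data.frame with `subject_id`, `n_fmri_runs`,
#'   `mean_fd_over_runs`, `mean_ad_over_runs`.
#' @export
subject_mean_motion <- function(summaries, protocol = default_protocol()) {
  keep <- summaries$run_label %in% fmri_runs(protocol)
  s <- summaries[keep, , drop = FALSE]
  if (!nrow(s))
    stop("no fMRI run summaries available for subject", call. = FALSE)
  data.frame(
    subject_id = s$subject_id[1],
    n_fmri_runs = nrow(s),
    mean_fd_over_runs = mean(s$mean_fd),
    mean_ad_over_runs = mean(s$mean_ad),
    stringsAsFactors = FALSE
  )
}

#' Cronbach's alpha across repeated runs
#'
#' Internal-consistency reliability of a per-run measure across the session,
#' treating runs as items and subjects as cases:
#' `alpha = k/(k-1) * (1 - sum of item variances / variance of item sums)`.
#' Only listwise-complete subjects enter.
#'
#' @param values numeric matrix or data.frame, subjects in rows, runs
#'   (items) in columns.
#' @return scalar alpha in (-Inf, 1].
#' @export
cronbach_alpha <- function(values) {
  m <- as.matrix(values)
  m <- m[stats::complete.cases(m), , drop = FALSE]
  k <- ncol(m)
  if (k < 2L) stop("need at least 2 runs (items)", call. = FALSE)
  if (nrow(m) < 3L) stop("need at least 3 complete subjects", call. = FALSE)
  total <- stats::var(rowSums(m))
  if (total <= .Machine$double.eps)
    stop("zero total variance: alpha undefined", call. = FALSE)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total)
}
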