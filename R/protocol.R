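#' Scan-protocol specification
#'
#' Describes a fixed MRI session protocol as an ordered table of runs, plus
#' the two denominators used for the scan quantity (completed runs) and scan
#' quality (included quality units) phenotypes. The default protocol is a
#' 60-minute paediatric session: three runs of a social-feedback task (SNAT),
#' two runs of a prosocial ball-tossing task (PCG), a structural T1 scan, two
#' diffusion (DTI) scans, and a final resting-state fMRI run.
#'
#' Quantity counts every run (9 by default). Quality counts rated/assessed
#' units (8 by default): each task run, the T1, the two DTI runs merged into
#' a single rated unit, and the resting-state run.
#'
#' @param runs data.frame with columns `run_label`, `modality` (one of
#'   `"task_fmri"`, `"t1"`, `"dti"`, `"rs_fmri"`), `nominal_volumes`,
#'   `nominal_minutes`.
#' @param tr_seconds repetition time of the fMRI runs, in seconds.
#' @param quantity_denominator number of runs counted for scan quantity.
#' @param quality_denominator number of quality units (DTI runs merged).
#' @return An object of class `mri_protocol`.
#' @export
mri_protocol <- function(runs,
                         tr_seconds = 2.2,
                         quantity_denominator = nrow(runs),
                         quality_denominator = NULL) {
  stopifnot(is.data.frame(runs),
            all(c("run_label", "modality", "nominal_volumes",
                  "nominal_minutes") %in% names(runs)))
  if (anyDuplicated(runs$run_label))
    stop("run labels must be unique", call. = FALSE)
  bad <- setdiff(runs$modality, c("task_fmri", "t1", "dti", "rs_fmri"))
  if (length(bad))
    stop("unknown modality: ", paste(bad, collapse = ", "), call. = FALSE)
  units <- .quality_units(runs)
  if (is.null(quality_denominator)) quality_denominator <- length(units)
  if (quality_denominator > quantity_denominator)
    stop("quality denominator cannot exceed quantity denominator",
         call. = FALSE)
  structure(list(runs = runs,
                 tr_seconds = tr_seconds,
                 quantity_denominator = as.integer(quantity_denominator),
                 quality_denominator = as.integer(quality_denominator)),
            class = "mri_protocol")
}

#' @rdname mri_protocol
#' @export
default_protocol <- function() {
  runs <- data.frame(
    run_label = c("snat1", "snat2", "snat3", "pcg1", "pcg2",
                  "t1", "dti1", "dti2", "rs"),
    modality = c(rep("task_fmri", 5), "t1", "dti", "dti", "rs_fmri"),
    nominal_volumes = c(148L, 142L, 141L, 136L, 136L, NA, NA, NA, 142L),
    nominal_minutes = c(5.43, 5.21, 5.17, 4.99, 4.99, 5.0, 5.0, 5.0, 5.21),
    stringsAsFactors = FALSE
  )
  mri_protocol(runs)
}

# Quality units: one per task run, T1 and RS; all DTI runs form one unit.
# Returns a named list mapping unit name -> character vector of run labels.
.quality_units <- function(runs) {
  units <- list()
  for (i in seq_len(nrow(runs))) {
    lab <- runs$run_label[i]
    mod <- runs$modality[i]
    if (mod == "dti") {
      units[["dti"]] <- c(units[["dti"]], lab)
    } else {
      units[[lab]] <- lab
    }
  }
  units
}

#' @export
print.mri_protocol <- function(x, ...) {
  cat("MRI protocol:", nrow(x$runs), "runs,",
      x$quantity_denominator, "quantity /",
      x$quality_denominator, "quality units\n")
  print(x$runs, row.names = FALSE)
  invisible(x)
}

#' Labels of fMRI runs (task + resting state) in a protocol
#' @param protocol an `mri_protocol`.
#' @return character vector of run labels.
#' @export
fmri_runs <- function(protocol) {
  with(protocol$runs, run_label[modality %in% c("task_fmri", "rs_fmri")])
}
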