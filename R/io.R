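#' Rigid-body motion trace for one run
#'
#' Container for the per-volume rigid-body realignment parameters of a single
#' MRI run: three rotations (radians) and three translations (mm) per volume,
#' the output format of standard motion-correction tools.
#'
#' @param rotations numeric N x 3 matrix of rotations in radians.
#' @param translations numeric N x 3 matrix of translations in mm.
#' @param subject_id,run_label identifiers.
#' @param tr_seconds repetition time in seconds.
#' @return An object of class `motion_trace`.
#' @export
motion_trace <- function(rotations, translations,
                         subject_id = NA_character_,
                         run_label = NA_character_,
                         tr_seconds = 2.2) {
  rotations <- as.matrix(rotations)
  translations <- as.matrix(translations)
  if (ncol(rotations) != 3L || ncol(translations) != 3L)
    stop("rotations and translations must each have 3 columns", call. = FALSE)
  if (nrow(rotations) != nrow(translations))
    stop("rotations and translations must have the same number of volumes",
         call. = FALSE)
  if (!all(is.finite(rotations)) || !all(is.finite(translations)))
    stop("motion parameters must be finite", call. = FALSE)
  structure(list(subject_id = subject_id,
                 run_label = run_label,
                 n_volumes = nrow(translations),
                 rotations = unname(rotations),
                 translations = unname(translations),
                 tr_seconds = tr_seconds),
            class = "motion_trace")
}

#' @export
print.motion_trace <- function(x, ...) {
  cat("motion_trace:", x$subject_id, "/", x$run_label, "-",
      x$n_volumes, "volumes (TR", x$tr_seconds, "s)\n")
  invisible(x)
}

#' Read a 6-column motion-parameter (.par) file
#'
#' Parses the plain-text per-volume format written by rigid-body motion
#' correction: one line per volume, six whitespace-separated numbers. By the
#' dominant convention columns 1-3 are rotations in radians and columns 4-6
#' translations in mm; set `par_order = "trans_rot"` for the
#' translation-first dialect.
#'
#' @param path path to the .par file.
#' @param par_order column convention, `"rot_trans"` (default) or
#'   `"trans_rot"`.
#' @inheritParams motion_trace
#' @return A [motion_trace()].
#' @export
read_motion_par <- function(path, par_order = c("rot_trans", "trans_rot"),
                            subject_id = NA_character_,
                            run_label = NA_character_,
                            tr_seconds = 2.2) {
  par_order <- match.arg(par_order)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) stop("empty motion-parameter file: ", path,
                           call. = FALSE)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("line ", lineno[which(nf != 6L)[1]], " of ", path, " has ",
         nf[which(nf != 6L)[1]], " fields (expected 6)", call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(fields)))
  if (anyNA(vals)) {
    bad <- ceiling(which(is.na(vals))[1] / 6)
    stop("non-numeric token on line ", lineno[bad], " of ", path,
         call. = FALSE)
  }
  m <- matrix(vals, ncol = 6L, byrow = TRUE)
  if (par_order == "rot_trans") {
    rot <- m[, 1:3, drop = FALSE]; trans <- m[, 4:6, drop = FALSE]
  } else {
    trans <- m[, 1:3, drop = FALSE]; rot <- m[, 4:6, drop = FALSE]
  }
  motion_trace(rot, trans, subject_id = subject_id, run_label = run_label,
               tr_seconds = tr_seconds)
}

#' Write a motion trace as a 6-column .par file
#'
#' Numbers are serialized with 6 significant digits; [read_motion_par()] on
#' the result reproduces the trace up to that precision.
#'
#' @param trace a [motion_trace()].
#' @param path output path.
#' @param par_order column convention, see [read_motion_par()].
#' @return `path`, invisibly.
#' @export
write_motion_par <- function(trace, path,
                             par_order = c("rot_trans", "trans_rot")) {
  par_order <- match.arg(par_order)
  stopifnot(inherits(trace, "motion_trace"))
  m <- if (par_order == "rot_trans")
    cbind(trace$rotations, trace$translations)
  else
    cbind(trace$translations, trace$rotations)
  lines <- apply(m, 1, function(r)
    paste(formatC(r, format = "g", digits = 6), collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

# Columns required in a cohort phenotype table.
.cohort_required <- c("subject_id", "pair_id", "twin_id", "birth_order",
                      "zygosity", "age", "sex")

#' Read a cohort phenotype table
#'
#' Reads the tab-separated cohort table: one row per child, with pair
#' membership, zygosity, run-completion flags (`completed_<run>`), structural
#' ratings (`rating_t1`, `rating_dti`) and distress ratings. Pairs with a
#' missing co-twin are retained but flagged (`complete_pair = FALSE`) and are
#' excluded from all pairwise statistics downstream.
#'
#' @param path TSV file path.
#' @return data.frame of class `twin_cohort` with a `complete_pair` column.
#' @export
read_cohort_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""))
  # all-NA numeric columns (e.g. absent parent post-scan ratings) come back
  # as logical; restore their numeric mode
  dist <- grep("^(tension|excitement)_", names(df))
  df[dist] <- lapply(df[dist], as.numeric)
  as_twin_cohort(df)
}

#' @rdname read_cohort_table
#' @param df a data.frame with the cohort columns.
#' @export
as_twin_cohort <- function(df) {
  miss <- setdiff(.cohort_required, names(df))
  if (length(miss))
    stop("cohort table missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df)) {
    bad <- setdiff(unique(df$zygosity), c("MZ", "DZ"))
    if (length(bad))
      stop("unknown zygosity code: ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(df$twin_id))
      stop("duplicate twin_id in cohort table", call. = FALSE)
    sizes <- table(df$pair_id)
    df$complete_pair <- as.vector(sizes[as.character(df$pair_id)] == 2L)
  } else {
    df$complete_pair <- logical(0)
  }
  class(df) <- c("twin_cohort", "data.frame")
  df
}

#' Write a cohort table to TSV
#' @param cohort a `twin_cohort` data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  utils::write.table(cohort, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as YAML; values present in the file override
#' the package defaults from [cohort_config()] and [qc_thresholds()].
#'
#' @param path YAML file path.
#' @return `read_pipeline_config`: a list with elements `cohort` (a
#'   [cohort_config()]) and `thresholds` (a [qc_thresholds()]).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(cohort_config, raw$cohort %||% list())
  thr <- do.call(qc_thresholds, raw$thresholds %||% list())
  list(cohort = cfg, thresholds = thr)
}

#' @rdname read_pipeline_config
#' @param config list to serialize.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write report tables
#'
#' Writes each result table of a pipeline report (or any named list of
#' data.frames) as a TSV file with a deterministic column order, plus a
#' `summary.json` carrying scalar results and provenance. Re-running on the
#' same input produces byte-identical files.
#'
#' @param tables named list of data.frames (and optionally a `summary` list).
#' @param dir output directory, created if needed.
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(tables, dir) {
  if (!length(tables)) stop("no tables to write", call. = FALSE)
  is_df <- vapply(tables, is.data.frame, logical(1))
  if (any(is_df) && any(vapply(tables[is_df], nrow, 0L) == 0L))
    stop("refusing to write empty result tables", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in sort(names(tables)[is_df])) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 6))
    utils::write.table(df[, sort(names(df)), drop = FALSE], f, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "NA")
    written <- c(written, f)
  }
  extras <- tables[!is_df]
  if (length(extras)) {
    f <- file.path(dir, "summary.json")
    jsonlite::write_json(extras, f, auto_unbox = TRUE, digits = 8,
                         pretty = TRUE)
    written <- c(written, f)
  }
  invisible(written)
}
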