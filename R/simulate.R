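#' Synthetic twin-cohort configuration
#'
#' Defaults emulate a large developmental twin study: 256 same-sex pairs
#' aged 7-9, 55% monozygotic, scanned with the fixed 9-run protocol of
#' [default_protocol()]. Motion is driven by a latent, ACE-structured
#' "motion propensity" acting multiplicatively on the log scale (motion is
#' non-negative and right-skewed), with default propensity shares
#' (a2, c2, e2) = (0.65, 0, 0.35). Scanner-related distress (tension and
#' excitement, rated by child, researcher and parent at three timepoints on
#' a 1-6 scale) decreases in tension and increases in excitement over the
#' session in expectation, and tension raises the per-run dropout hazard,
#' which itself jumps after the structural T1 scan.
#'
#' @param n_pairs number of twin pairs.
#' @param prop_mz proportion of monozygotic pairs (rounded half up).
#' @param protocol an [mri_protocol()].
#' @param motion list of motion-model parameters: ACE shares of the log
#'   propensity (`a2`, `c2`, `e2`), `sigma_log` (SD of the log propensity),
#'   `baseline_fd` (approximate mean FD in mm at unit propensity),
#'   `drift_sd` (slow-drift amplitude SD, mm), `ar_phi` (jitter
#'   autocorrelation), `spike_rate` (per volume), `spike_mag` (mm),
#'   `run_slope` (within-session increase per protocol position),
#'   `rot_scale` (rad of rotation per mm of the shared latent process).
#' @param distress list: `tension_means`, `excitement_means` (length-3 child
#'   means per timepoint), ACE shares of the latent distress, `te_cor`
#'   (tension-excitement correlation, negative), rater loadings and biases,
#'   `scale_range`, and `completion_beta` (effect of standardized tension on
#'   the log dropout hazard).
#' @param attrition list: `p_never_start`, `hazard_pre_t1`,
#'   `hazard_post_t1` (per-run dropout probabilities).
#' @param rating list: `noise_sd` and the 4-level marginal distributions
#'   `t1_probs`, `dti_probs` (Excellent/Good/Doubtful/Failed).
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_pairs = 256,
                          prop_mz = 0.55,
                          protocol = default_protocol(),
                          motion = list(),
                          distress = list(),
                          attrition = list(),
                          rating = list()) {
  motion <- utils::modifyList(list(
    a2 = 0.65, c2 = 0.00, e2 = 0.35,
    sigma_log = 0.5, baseline_fd = 0.25, drift_sd = 0.3,
    ar_phi = 0.9, spike_rate = 0.01, spike_mag = 0.8,
    run_slope = 0.05, rot_scale = 1 / 50), motion)
  distress <- utils::modifyList(list(
    tension_means = c(3.84, 3.28, 2.62),
    excitement_means = c(4.72, 5.10, 4.95),
    a2 = 0.10, c2 = 0.35, e2 = 0.55,
    te_cor = -0.35, latent_sd = 1.0,
    researcher_loading = 0.9, parent_loading = 0.45,
    researcher_bias = 0.3, parent_bias = 0.3,
    rater_noise = 0.5, scale_range = c(1, 6),
    completion_beta = 0.5), distress)
  attrition <- utils::modifyList(list(
    p_never_start = 0.047,
    hazard_pre_t1 = 0.004,
    hazard_post_t1 = 0.034), attrition)
  rating <- utils::modifyList(list(
    noise_sd = 1.2,
    t1_probs = c(0.31, 0.43, 0.16, 0.10),
    dti_probs = c(0.86, 0.08, 0.04, 0.02)), rating)
  stopifnot(n_pairs >= 1, prop_mz >= 0, prop_mz <= 1,
            inherits(protocol, "mri_protocol"))
  for (sh in list(c(motion$a2, motion$c2, motion$e2),
                  c(distress$a2, distress$c2, distress$e2))) {
    if (any(sh < 0) || abs(sum(sh) - 1) > 1e-8)
      stop("ACE shares must be non-negative and sum to 1", call. = FALSE)
  }
  probs <- c(attrition$p_never_start, attrition$hazard_pre_t1,
             attrition$hazard_post_t1, motion$spike_rate)
  if (any(probs < 0 | probs > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(n_pairs = n_pairs, prop_mz = prop_mz, protocol = protocol,
                 motion = motion, distress = distress,
                 attrition = attrition, rating = rating),
            class = "cohort_config")
}

# Named substreams off one root seed: each generation stage reseeds from a
# fixed offset so stages are independently reproducible. Kept below 2^31.
.stage_seed <- function(seed, stage) {
  k <- match(stage, c("phenotypes", "subjects", "distress", "traces"))
  as.integer((as.numeric(seed) * 7 + k * 1000003) %% 2147483629)
}

#' Simulate ACE-structured twin phenotypes
#'
#' Draws each pair from the bivariate normal implied by the twin model:
#' common mean, common variance, within-pair correlation `a2 + c2` for MZ
#' and `0.5 * a2 + c2` for DZ pairs.
#'
#' @param n_mz,n_dz numbers of MZ and DZ pairs.
#' @param a2,c2,e2 standardized variance shares, non-negative, summing to 1.
#' @param mu phenotype mean.
#' @param total_var phenotypic variance.
#' @param seed optional seed (left untouched if `NULL`, so the call can be
#'   embedded in a larger reproducible stream).
#' @return a [twin_pairs()] table.
#' @export
generate_twin_phenotypes <- function(n_mz, n_dz, a2, c2, e2 = 1 - a2 - c2,
                                     mu = 0, total_var = 1, seed = NULL) {
  sh <- c(a2, c2, e2)
  if (any(sh < -1e-12) || abs(sum(sh) - 1) > 1e-8)
    stop("shares must be non-negative and sum to 1", call. = FALSE)
  stopifnot(total_var > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- n_mz + n_dz
  zyg <- rep(c("MZ", "DZ"), c(n_mz, n_dz))
  rho <- ifelse(zyg == "MZ", a2 + c2, 0.5 * a2 + c2)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  x1 <- z1
  x2 <- rho * z1 + sqrt(pmax(0, 1 - rho^2)) * z2
  s <- sqrt(total_var)
  out <- data.frame(pair_id = sprintf("P%04d", seq_len(n)),
                    zygosity = zyg,
                    value_twin1 = mu + s * x1,
                    value_twin2 = mu + s * x2,
                    stringsAsFactors = FALSE)
  class(out) <- c("twin_pairs", "data.frame")
  out
}

# One simulated run trace: slow drift + AR(1) jitter + sparse spikes per
# axis, everything scaled multiplicatively, so all displacement metrics are
# exactly linear in `scale`.
.sim_run_trace <- function(n_volumes, scale, mult, motion) {
  axis_proc <- function() {
    amp <- motion$drift_sd * stats::runif(1, 0.75, 1.25)
    f <- stats::runif(1, 0.5, 1.5)
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- amp * sin(2 * pi * f * seq_len(n_volumes) / n_volumes + phase)
    innov <- stats::rnorm(n_volumes, 0, motion$baseline_fd / 5)
    ar <- as.numeric(stats::filter(innov, motion$ar_phi,
                                   method = "recursive"))
    spikes <- numeric(n_volumes)
    hit <- stats::runif(n_volumes) < motion$spike_rate
    if (any(hit))
      spikes[hit] <- sample(c(-1, 1), sum(hit), replace = TRUE) *
        stats::rexp(sum(hit), 1 / motion$spike_mag)
    drift + ar + spikes
  }
  trans <- scale * mult * cbind(axis_proc(), axis_proc(), axis_proc())
  rot <- scale * mult * motion$rot_scale *
    cbind(axis_proc(), axis_proc(), axis_proc())
  list(rotations = rot, translations = trans)
}

#' Simulate motion traces for completed fMRI runs
#'
#' Each trace is a smooth sinusoidal drift plus autocorrelated jitter plus a
#' sparse spike process, all scaled by `exp(sigma_log * propensity)` and by
#' a within-session multiplier `1 + run_slope * (position - 1)`, so later
#' runs carry stochastically more motion. Everything is linear in the scale:
#' a subject with propensity `-Inf` produces all-zero traces, and doubling
#' the scale doubles every displacement metric.
#'
#' @param records cohort rows with `motion_propensity` and completion flags.
#' @param config a [cohort_config()].
#' @param seed seed for the trace substream.
#' @return named list of [motion_trace()] objects, names
#'   `<subject_id>.<run_label>`.
#' @export
generate_motion_traces <- function(records, config, seed) {
  set.seed(seed)
  runs <- config$protocol$runs
  fmri <- runs$run_label[runs$modality %in% c("task_fmri", "rs_fmri")]
  traces <- list()
  for (i in seq_len(nrow(records))) {
    rec <- records[i, ]
    scale <- exp(config$motion$sigma_log * rec$motion_propensity)
    for (lab in fmri) {
      if (!isTRUE(rec[[paste0("completed_", lab)]])) next
      pos <- match(lab, runs$run_label)
      nv <- runs$nominal_volumes[pos]
      mult <- 1 + config$motion$run_slope * (pos - 1)
      pr <- .sim_run_trace(nv, scale, mult, config$motion)
      traces[[paste(rec$subject_id, lab, sep = ".")]] <-
        motion_trace(pr$rotations, pr$translations,
                     subject_id = rec$subject_id, run_label = lab,
                     tr_seconds = config$protocol$tr_seconds)
    }
  }
  traces
}

.clamp_rating <- function(x, range) {
  pmin(pmax(round(x), range[1]), range[2])
}

#' Simulate distress ratings, run completion and structural ratings
#'
#' Latent tension and excitement are ACE-structured and negatively
#' correlated; child ratings follow timepoint means with tension falling
#' and excitement rising across the session, and researcher/parent ratings
#' load on the same latent (parents rate only the first two timepoints, as
#' they are absent after the scan). Completion is sequential: a never-start
#' probability, then a per-run dropout hazard that jumps after the T1
#' position and scales with `exp(completion_beta * standardized tension)`.
#' Structural T1/DTI ratings come from an ordinal cut of the motion
#' propensity plus noise, calibrated to the configured marginals.
#'
#' @param records cohort rows with `motion_propensity`.
#' @param config a [cohort_config()].
#' @param seed seed for the distress/attrition substream.
#' @return `records` augmented with distress columns
#'   (`<scale>_<rater>_t<1:3>`), `completed_<run>` flags and
#'   `rating_t1` / `rating_dti`.
#' @export
generate_distress_and_attrition <- function(records, config, seed) {
  set.seed(seed)
  dcfg <- config$distress
  n_pairs <- nrow(records) / 2
  ord <- order(records$pair_id, records$birth_order)
  records <- records[ord, ]
  zyg_pair <- records$zygosity[seq(1, nrow(records), by = 2)]
  n_mz <- sum(zyg_pair == "MZ")

  latent <- function() {
    ph <- generate_twin_phenotypes(n_mz, n_pairs - n_mz,
                                   dcfg$a2, dcfg$c2, dcfg$e2)
    # unstack to per-subject order (pairs sorted MZ first in ph; remap)
    v <- numeric(nrow(records))
    mzp <- which(zyg_pair == "MZ"); dzp <- which(zyg_pair != "MZ")
    pair_rows <- c(mzp, dzp)
    for (j in seq_along(pair_rows)) {
      p <- pair_rows[j]
      v[2 * p - 1] <- ph$value_twin1[j]
      v[2 * p] <- ph$value_twin2[j]
    }
    v
  }
  lt <- latent()
  le_raw <- latent()
  le <- dcfg$te_cor * lt + sqrt(1 - dcfg$te_cor^2) * le_raw

  rng <- dcfg$scale_range
  for (t in 1:3) {
    tm <- dcfg$tension_means[t]; em <- dcfg$excitement_means[t]
    records[[paste0("tension_child_t", t)]] <- .clamp_rating(
      tm + dcfg$latent_sd * lt + stats::rnorm(nrow(records), 0, 0.4), rng)
    records[[paste0("excitement_child_t", t)]] <- .clamp_rating(
      em + dcfg$latent_sd * le + stats::rnorm(nrow(records), 0, 0.4), rng)
    for (rater in c("researcher", "parent")) {
      if (rater == "parent" && t == 3) {
        records[[paste0("tension_parent_t", t)]] <- NA_real_
        records[[paste0("excitement_parent_t", t)]] <- NA_real_
        next
      }
      load <- dcfg[[paste0(rater, "_loading")]]
      bias <- dcfg[[paste0(rater, "_bias")]]
      records[[paste0("tension_", rater, "_t", t)]] <- .clamp_rating(
        tm + bias + dcfg$latent_sd * load * lt +
          stats::rnorm(nrow(records), 0, dcfg$rater_noise), rng)
      records[[paste0("excitement_", rater, "_t", t)]] <- .clamp_rating(
        em - bias + dcfg$latent_sd * load * le +
          stats::rnorm(nrow(records), 0, dcfg$rater_noise), rng)
    }
  }

  # sequential completion: never-start, then per-run dropout
  acfg <- config$attrition
  runs <- config$protocol$runs
  t1_pos <- match("t1", runs$run_label)
  if (is.na(t1_pos)) t1_pos <- nrow(runs) + 1L
  tension_std <- as.numeric(scale(lt))
  started <- stats::runif(nrow(records)) >= acfg$p_never_start
  flags <- matrix(FALSE, nrow(records), nrow(runs))
  for (i in seq_len(nrow(records))) {
    if (!started[i]) next
    mod <- exp(dcfg$completion_beta * tension_std[i])
    for (p in seq_len(nrow(runs))) {
      h <- if (p > t1_pos) acfg$hazard_post_t1 else acfg$hazard_pre_t1
      if (stats::runif(1) < min(1, h * mod)) break
      flags[i, p] <- TRUE
    }
  }
  for (p in seq_len(nrow(runs)))
    records[[paste0("completed_", runs$run_label[p])]] <- flags[, p]

  # ordinal structural ratings driven by motion propensity
  rcfg <- config$rating
  lat_sd <- sqrt(1 + rcfg$noise_sd^2)
  rate_scan <- function(probs, completed) {
    lat <- records$motion_propensity +
      stats::rnorm(nrow(records), 0, rcfg$noise_sd)
    cuts <- stats::qnorm(cumsum(probs)[1:3], sd = lat_sd)
    r <- .rating_levels[findInterval(lat, cuts) + 1L]
    r[!completed] <- NA_character_
    r
  }
  records$rating_t1 <- rate_scan(rcfg$t1_probs, records$completed_t1)
  dti_runs <- runs$run_label[runs$modality == "dti"]
  dti_done <- Reduce(`&`, lapply(dti_runs, function(l)
    records[[paste0("completed_", l)]]))
  records$rating_dti <- rate_scan(rcfg$dti_probs, dti_done)
  records
}

#' Generate a full synthetic twin cohort
#'
#' Orchestrates the generation stages (phenotypes, subjects, distress and
#' attrition, motion traces) off one root seed via fixed substreams, so the
#' result is fully deterministic given `(config, seed)`. With `dir` set, the
#' cohort is also written to disk in exactly the formats the readers accept:
#' `cohort.tsv`, one `.par` file per completed fMRI run under `par/`, and a
#' `config.yaml` echo.
#'
#' @param config a [cohort_config()].
#' @param seed integer root seed.
#' @param dir optional output directory.
#' @return list of class `twin_cohort_sim`: `records` (a `twin_cohort`
#'   data.frame), `traces` (named list of [motion_trace()]), `config`,
#'   `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1,
                            dir = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  n_mz <- floor(config$n_pairs * config$prop_mz + 0.5)  # round half up
  n_dz <- config$n_pairs - n_mz

  prop <- generate_twin_phenotypes(n_mz, n_dz,
                                   config$motion$a2, config$motion$c2,
                                   config$motion$e2,
                                   seed = .stage_seed(seed, "phenotypes"))

  set.seed(.stage_seed(seed, "subjects"))
  n_sub <- 2L * config$n_pairs
  pair_id <- rep(sprintf("P%04d", seq_len(config$n_pairs)), each = 2)
  zyg <- rep(prop$zygosity, each = 2)
  age_pair <- pmin(pmax(stats::rnorm(config$n_pairs, 7.94, 0.67), 7), 9.99)
  sex_pair <- sample(c("M", "F"), config$n_pairs, replace = TRUE,
                     prob = c(0.49, 0.51))
  records <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_sub)),
    pair_id = pair_id,
    twin_id = sprintf("S%04d", seq_len(n_sub)),
    birth_order = rep(1:2, config$n_pairs),
    zygosity = zyg,
    age = round(rep(age_pair, each = 2), 2),
    sex = rep(sex_pair, each = 2),
    motion_propensity = as.vector(rbind(prop$value_twin1,
                                        prop$value_twin2)),
    stringsAsFactors = FALSE
  )

  records <- generate_distress_and_attrition(
    records, config, .stage_seed(seed, "distress"))
  traces <- generate_motion_traces(
    records, config, .stage_seed(seed, "traces"))

  cohort <- structure(list(records = as_twin_cohort(records),
                           traces = traces,
                           config = config, seed = seed),
                      class = "twin_cohort_sim")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.twin_cohort_sim <- function(x, ...) {
  cat("Synthetic twin cohort:", nrow(x$records) / 2, "pairs (",
      sum(x$records$zygosity == "MZ") / 2, "MZ ),",
      length(x$traces), "motion traces, seed", x$seed, "\n")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' @param cohort a `twin_cohort_sim` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "par"), recursive = TRUE, showWarnings = FALSE)
  write_cohort_table(cohort$records, file.path(dir, "cohort.tsv"))
  for (nm in names(cohort$traces)) {
    tr <- cohort$traces[[nm]]
    write_motion_par(tr, file.path(dir, "par",
                                   paste0(tr$subject_id, "_",
                                          tr$run_label, ".par")))
  }
  cfg <- cohort$config
  yaml::write_yaml(list(n_pairs = cfg$n_pairs, prop_mz = cfg$prop_mz,
                        motion = cfg$motion, distress = cfg$distress,
                        attrition = cfg$attrition, rating = cfg$rating,
                        seed = cohort$seed),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}
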