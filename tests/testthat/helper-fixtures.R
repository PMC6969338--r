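# Small in-code fixtures shared across test files.

# Trace with explicit parameter matrices (defaults: all zero).
make_trace <- function(n = 5, rot = NULL, trans = NULL, run = "snat1",
                       subject = "S0001") {
  if (is.null(rot)) rot <- matrix(0, n, 3)
  if (is.null(trans)) trans <- matrix(0, n, 3)
  motion_trace(rot, trans, subject_id = subject, run_label = run)
}

# Random smooth-ish trace for property tests.
random_trace <- function(n = 30, sd = 0.2, run = "snat1") {
  make_trace(n,
             rot = matrix(rnorm(3 * n, 0, sd / 50), n, 3),
             trans = matrix(rnorm(3 * n, 0, sd), n, 3),
             run = run)
}

# Scale every rigid-body parameter of a trace by lambda.
scale_trace <- function(trace, lambda) {
  motion_trace(trace$rotations * lambda, trace$translations * lambda,
               subject_id = trace$subject_id, run_label = trace$run_label,
               tr_seconds = trace$tr_seconds)
}

# Minimal cohort data.frame: `values` optional phenotype column.
make_cohort <- function(n_pairs = 4, zygosity = rep(c("MZ", "DZ"),
                                                    length.out = n_pairs)) {
  n <- 2 * n_pairs
  as_twin_cohort(data.frame(
    subject_id = sprintf("S%02d", 1:n),
    pair_id = rep(sprintf("P%02d", 1:n_pairs), each = 2),
    twin_id = sprintf("S%02d", 1:n),
    birth_order = rep(1:2, n_pairs),
    zygosity = rep(zygosity, each = 2),
    age = 8, sex = "F",
    stringsAsFactors = FALSE
  ))
}

# One-row run summary with chosen fields, for QC rule tests.
fake_summary <- function(run_label = "snat1", max_abs = 0, f03 = 0,
                         f05 = 0, mean_fd = 0.1, mean_ad = 0.2,
                         subject = "S01") {
  data.frame(subject_id = subject, run_label = run_label, n_volumes = 100,
             mean_fd = mean_fd, mean_ad_x = mean_ad, mean_ad_y = mean_ad,
             mean_ad_z = mean_ad, mean_ad = mean_ad,
             max_abs_per_axis = max_abs,
             frac_flagged_03 = f03, frac_flagged_05 = f05,
             stringsAsFactors = FALSE)
}

# Cohort record with all protocol runs completed and top ratings.
clean_record <- function(protocol = default_protocol()) {
  rec <- data.frame(subject_id = "S01", rating_t1 = "Excellent",
                    rating_dti = "Excellent", stringsAsFactors = FALSE)
  for (lab in protocol$runs$run_label)
    rec[[paste0("completed_", lab)]] <- TRUE
  rec
}

# Clean run summaries for every fMRI run of the protocol.
clean_summaries <- function(protocol = default_protocol()) {
  do.call(rbind, lapply(fmri_runs(protocol), function(l)
    fake_summary(run_label = l)))
}
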