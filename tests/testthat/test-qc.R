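test_that("task-run inclusion applies the strict 3 mm rule", {
  thr <- qc_thresholds()
  expect_true(classify_task_run(fake_summary(max_abs = 0), thr))
  expect_true(classify_task_run(fake_summary(max_abs = 2.9), thr))
  expect_false(classify_task_run(fake_summary(max_abs = 3.0), thr))
  expect_false(classify_task_run(fake_summary(max_abs = 10), thr))
})

test_that("resting-state inclusion uses flagged fractions strictly below 20%", {
  thr <- qc_thresholds()
  clean <- fake_summary("rs")
  for (s in c("stringent", "lenient", "ad3"))
    expect_true(classify_rs_run(clean, s, thr))

  # 142-volume run has 141 FD frames; 28 flagged ~ 19.9%, 29 ~ 20.6%
  expect_true(classify_rs_run(fake_summary("rs", f03 = 28 / 141),
                              "stringent", thr))
  expect_false(classify_rs_run(fake_summary("rs", f03 = 29 / 141),
                               "stringent", thr))
  expect_false(classify_rs_run(fake_summary("rs", f03 = 0.20),
                               "stringent", thr))
  # ad3 variant applies the task rule
  expect_false(classify_rs_run(fake_summary("rs", max_abs = 3.5),
                               "ad3", thr))
  expect_error(classify_rs_run(clean, "bogus", thr))
})

test_that("any run included under stringent is included under lenient", {
  set.seed(21)
  for (i in 1:50) {
    f03 <- runif(1, 0, 0.5)
    f05 <- runif(1, 0, f03)  # flagged fractions are nested by construction
    s <- fake_summary("rs", f03 = f03, f05 = f05)
    if (classify_rs_run(s, "stringent"))
      expect_true(classify_rs_run(s, "lenient"))
  }
})

test_that("manual ratings include by stringency, Failed never", {
  expect_true(classify_rated_scan("Excellent", "stringent"))
  expect_true(classify_rated_scan("Good", "stringent"))
  expect_false(classify_rated_scan("Doubtful", "stringent"))
  expect_true(classify_rated_scan("Doubtful", "lenient"))
  expect_false(classify_rated_scan("Failed", "lenient"))
  expect_false(classify_rated_scan(NA_character_, "lenient"))
  expect_error(classify_rated_scan("Superb", "stringent"), "unknown rating")
})

test_that("scan quantity counts completed runs out of 9", {
  rec <- clean_record()
  expect_equal(scan_quantity(rec), 9L)

  none <- rec
  none[grep("^completed_", names(none))] <- FALSE
  expect_equal(scan_quantity(none), 0L)

  six <- none
  for (l in c("snat1", "snat2", "snat3", "pcg1", "pcg2", "t1"))
    six[[paste0("completed_", l)]] <- TRUE
  expect_equal(scan_quantity(six), 6L)

  bad <- rec; bad$completed_extra <- TRUE
  expect_error(scan_quantity(bad), "not in the protocol")
})

test_that("scan quality counts included units over completed units", {
  rec <- clean_record()
  sm <- clean_summaries()
  q <- scan_quality(rec, sm)
  expect_equal(q$n_included, 8L)
  expect_equal(q$included_fraction, 1.0)

  # all completed, RS excluded only -> 7 of 8
  sm_rs <- sm
  sm_rs$frac_flagged_03[sm_rs$run_label == "rs"] <- 0.5
  q2 <- scan_quality(rec, sm_rs)
  expect_equal(q2$n_included, 7L)
  expect_equal(q2$included_fraction, 7 / 8)

  # only 4 quality units completed, all clean -> (4, 1.0)
  rec4 <- rec
  for (l in c("pcg2", "t1", "dti1", "dti2", "rs"))
    rec4[[paste0("completed_", l)]] <- FALSE
  q3 <- scan_quality(rec4, sm)
  expect_equal(q3$n_included, 4L)
  expect_equal(q3$included_fraction, 1.0)

  # nothing completed: fraction undefined, not zero
  rec0 <- rec
  rec0[grep("^completed_", names(rec0))] <- FALSE
  expect_true(is.na(scan_quality(rec0, sm)$included_fraction))

  # one missing DTI run voids the merged DTI unit
  rec_d <- rec; rec_d$completed_dti2 <- FALSE
  qd <- scan_quality(rec_d, sm)
  expect_equal(qd$n_completed_units, 7L)
  expect_false(qd$unit_completed[["dti"]])
})

test_that("motion strata nest and follow the printed bounds", {
  expect_equal(as.character(motion_stratum(0.1, 0.5)), "minimal")
  expect_equal(as.character(motion_stratum(0.5, 2.0)), "moderate")
  expect_equal(as.character(motion_stratum(2.0, 10)), "excessive")
  # boundary values fall outside (strict inequalities)
  expect_equal(as.character(motion_stratum(0.3, 0.5)), "moderate")
  expect_equal(as.character(motion_stratum(1.0, 2.0)), "excessive")
  # a minimal subject always satisfies the moderate bounds
  thr <- qc_thresholds()
  set.seed(22)
  fd <- runif(200, 0, 2); ad <- runif(200, 0, 5)
  st <- motion_stratum(fd, ad, thr)
  expect_true(all(fd[st == "minimal"] < thr$moderate_mean_fd &
                    ad[st == "minimal"] < thr$moderate_mean_ad))
})

test_that("time-window inclusion nests 60 within 45 within 30", {
  rec <- clean_record()
  sm <- clean_summaries()
  for (w in c(30, 45, 60))
    expect_true(time_window_inclusion(rec, sm, w))

  # RS excluded only: 30 and 45 min unaffected, 60 min fails
  sm_rs <- sm
  sm_rs$frac_flagged_03[sm_rs$run_label == "rs"] <- 0.5
  expect_true(time_window_inclusion(rec, sm_rs, 30))
  expect_true(time_window_inclusion(rec, sm_rs, 45))
  expect_false(time_window_inclusion(rec, sm_rs, 60))

  expect_error(time_window_inclusion(rec, sm, 40), "unsupported window")

  # nesting property over randomized motion
  set.seed(23)
  for (i in 1:25) {
    smr <- sm
    smr$max_abs_per_axis <- runif(nrow(smr), 0, 5)
    smr$frac_flagged_03 <- runif(nrow(smr), 0, 0.4)
    recr <- rec
    recr$rating_t1 <- sample(c("Excellent", "Doubtful", "Failed"), 1)
    w30 <- time_window_inclusion(recr, smr, 30)
    w45 <- time_window_inclusion(recr, smr, 45)
    w60 <- time_window_inclusion(recr, smr, 60)
    expect_true(!w60 || w45)
    expect_true(!w45 || w30)
  }
})

test_that("inflating motion never flips an exclusion to an inclusion", {
  set.seed(24)
  rec <- clean_record()
  for (i in 1:20) {
    sm <- clean_summaries()
    sm$max_abs_per_axis <- runif(nrow(sm), 0, 4)
    sm$frac_flagged_03 <- runif(nrow(sm), 0, 0.4)
    sm$frac_flagged_05 <- sm$frac_flagged_03 * runif(nrow(sm))
    worse <- sm
    worse$max_abs_per_axis <- worse$max_abs_per_axis * 1.7
    worse$frac_flagged_03 <- pmin(1, worse$frac_flagged_03 * 1.7)
    worse$frac_flagged_05 <- pmin(1, worse$frac_flagged_05 * 1.7)
    expect_lte(scan_quality(rec, worse)$n_included,
               scan_quality(rec, sm)$n_included)
  }
})
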