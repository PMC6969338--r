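test_that("twin phenotypes realize the implied correlation structure", {
  # e2 = 1: co-twins independent
  set.seed(51)
  ind <- generate_twin_phenotypes(4000, 4000, 0, 0, 1)
  for (z in c("MZ", "DZ")) {
    s <- ind[ind$zygosity == z, ]
    expect_lt(abs(cor(s$value_twin1, s$value_twin2)), 0.05)
  }

  # c2 = 1: twins are exact copies in both zygosity groups
  dup <- generate_twin_phenotypes(50, 50, 0, 1, 0, seed = 52)
  expect_equal(dup$value_twin2, dup$value_twin1)

  # default motion shares: rMZ ~ 0.65, rDZ ~ 0.325 within 3 MC SEs
  big <- generate_twin_phenotypes(10000, 10000, 0.65, 0, 0.35, seed = 53)
  r <- sapply(c("MZ", "DZ"), function(z) {
    s <- big[big$zygosity == z, ]
    cor(s$value_twin1, s$value_twin2)
  })
  se <- function(rho) (1 - rho^2) / sqrt(10000)
  expect_lt(abs(r[["MZ"]] - 0.65), 3 * se(0.65))
  expect_lt(abs(r[["DZ"]] - 0.325), 3 * se(0.325))

  expect_error(generate_twin_phenotypes(5, 5, 0.7, 0.5, 0.3), "sum to 1")
  expect_error(generate_twin_phenotypes(5, 5, -0.1, 0.4, 0.7), "sum to 1")
})

test_that("cohort generation is deterministic and rounds MZ count half up", {
  cfg <- cohort_config(n_pairs = 20)
  a <- generate_cohort(cfg, seed = 9)
  b <- generate_cohort(cfg, seed = 9)
  expect_identical(a$records, b$records)
  expect_identical(a$traces, b$traces)
  c2 <- generate_cohort(cfg, seed = 10)
  expect_false(identical(a$records$motion_propensity,
                         c2$records$motion_propensity))

  # 256 x 0.55 = 140.8 -> 141 MZ pairs = 282 MZ subjects
  full <- generate_cohort(cohort_config(n_pairs = 256), seed = 1)
  expect_equal(sum(full$records$zygosity == "MZ"), 282L)
  # and both co-twins share pair id and zygosity
  expect_true(all(tapply(full$records$zygosity, full$records$pair_id,
                         function(z) length(unique(z)) == 1)))
})

test_that("written cohorts read back identically", {
  d <- withr::local_tempdir()
  co <- generate_cohort(cohort_config(n_pairs = 8), seed = 3, dir = d)
  expect_true(file.exists(file.path(d, "cohort.tsv")))
  expect_true(file.exists(file.path(d, "config.yaml")))

  back <- read_cohort_table(file.path(d, "cohort.tsv"))
  expect_equal(as.data.frame(back), as.data.frame(co$records))

  pars <- list.files(file.path(d, "par"), full.names = TRUE)
  expect_length(pars, length(co$traces))
  tr0 <- co$traces[[1]]
  tr1 <- read_motion_par(file.path(d, "par", paste0(tr0$subject_id, "_",
                                                    tr0$run_label, ".par")))
  expect_equal(tr1$translations, tr0$translations, tolerance = 1e-5)

  # rewriting produces byte-identical files
  d2 <- withr::local_tempdir()
  write_cohort(co, d2)
  expect_identical(unname(tools::md5sum(file.path(d, "cohort.tsv"))),
                   unname(tools::md5sum(file.path(d2, "cohort.tsv"))))
})

test_that("trace mechanics are linear in the propensity scale", {
  cfg <- cohort_config()
  set.seed(54); t1 <- twinmotion:::.sim_run_trace(60, 1, 1, cfg$motion)
  set.seed(54); t2 <- twinmotion:::.sim_run_trace(60, 2, 1, cfg$motion)
  expect_equal(t2$translations, 2 * t1$translations)
  expect_equal(t2$rotations, 2 * t1$rotations)

  # zero scale (propensity -> -Inf limit): all-zero traces, zero metrics
  set.seed(54); t0 <- twinmotion:::.sim_run_trace(60, 0, 1, cfg$motion)
  expect_true(all(t0$translations == 0) && all(t0$rotations == 0))
  tr0 <- motion_trace(t0$rotations, t0$translations)
  expect_equal(mean(framewise_displacement(tr0)), 0)
  expect_equal(max(absolute_displacement(tr0)), 0)
})

test_that("head motion increases over the session in the generated cohort", {
  co <- generate_cohort(cohort_config(n_pairs = 60), seed = 5)
  sm <- do.call(rbind, lapply(co$traces, summarize_run))
  first <- sm$mean_fd[sm$run_label == "snat1"]
  last <- sm$mean_fd[sm$run_label == "rs"]
  expect_gt(length(first), 100)
  expect_gt(mean(last), mean(first))
})

test_that("distress shapes completion with the configured signs", {
  co <- generate_cohort(cohort_config(n_pairs = 256), seed = 6)
  r <- co$records
  q <- scan_quantity(r)
  expect_gt(length(q), 500)
  expect_gt(cor(r$excitement_child_t2, q), 0)
  expect_lt(cor(r$tension_child_t2, q), 0)
  # tension and excitement are negatively related
  expect_lt(cor(r$tension_child_t1, r$excitement_child_t1), 0)
  # tension falls, excitement rises from simulation to scan
  expect_gt(mean(r$tension_child_t1), mean(r$tension_child_t3))
  expect_lt(mean(r$excitement_child_t1), mean(r$excitement_child_t2))
  # parents are absent after the scan
  expect_true(all(is.na(r$tension_parent_t3)))
  # raters track the child's state
  expect_gt(cor(r$tension_child_t1, r$tension_researcher_t1), 0.4)

  # zero completion effect: tension no longer predicts quantity
  cfg0 <- cohort_config(n_pairs = 256, distress = list(completion_beta = 0))
  co0 <- generate_cohort(cfg0, seed = 6)
  q0 <- scan_quantity(co0$records)
  expect_lt(abs(cor(co0$records$tension_child_t2, q0)), 0.1)

  # no hazards at all: everyone completes all 9 runs
  cfg1 <- cohort_config(n_pairs = 30,
                        attrition = list(p_never_start = 0,
                                         hazard_pre_t1 = 0,
                                         hazard_post_t1 = 0))
  co1 <- generate_cohort(cfg1, seed = 7)
  expect_true(all(scan_quantity(co1$records) == 9L))
})

test_that("with no genetic share, MZ and DZ pair differences are exchangeable", {
  ph <- generate_twin_phenotypes(3000, 3000, 0, 0.5, 0.5, seed = 58)
  d <- abs(ph$value_twin1 - ph$value_twin2)
  ks <- suppressWarnings(ks.test(d[ph$zygosity == "MZ"],
                                 d[ph$zygosity == "DZ"]))
  expect_gt(ks$p.value, 0.01)
})
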