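test_that("ACE negative log-likelihood matches closed forms and a density oracle", {
  one <- data.frame(zygosity = "MZ", value_twin1 = 0, value_twin2 = 0)
  # a = c = 0, e = 1: two independent standard normals at 0
  expect_equal(-ace_neg_loglik(c(0, 0, 1, 0), one),
               2 * dnorm(0, log = TRUE))

  # symmetric in twin order
  set.seed(41)
  pairs <- generate_twin_phenotypes(6, 5, 0.4, 0.3, 0.3)
  swapped <- pairs
  swapped$value_twin1 <- pairs$value_twin2
  swapped$value_twin2 <- pairs$value_twin1
  par <- c(0.6, 0.4, 0.7, 0.1)
  expect_equal(ace_neg_loglik(par, swapped), ace_neg_loglik(par, pairs))

  # independent bivariate-normal density via the conditional factorization
  biv_logdens <- function(x1, x2, mu, v, cv) {
    dnorm(x1, mu, sqrt(v), log = TRUE) +
      dnorm(x2, mu + cv / v * (x1 - mu), sqrt(v - cv^2 / v), log = TRUE)
  }
  a <- 0.5; cc <- 0.3; e <- 0.8; mu <- 0.2
  v <- a^2 + cc^2 + e^2
  ll <- 0
  for (i in seq_len(nrow(pairs))) {
    phi <- if (pairs$zygosity[i] == "MZ") 1 else 0.5
    ll <- ll + biv_logdens(pairs$value_twin1[i], pairs$value_twin2[i],
                           mu, v, phi * a^2 + cc^2)
  }
  expect_equal(ace_neg_loglik(c(a, cc, e, mu), pairs), -ll)

  # singular covariance (e = 0) is rejected with a large value
  expect_gt(ace_neg_loglik(c(1, 0, 0, 0), pairs), 1e100)
})

test_that("Falconer identities evaluate, clip and renormalize", {
  expect_equal(falconer_estimates(0.4, 0.4)$A, 0)
  f <- falconer_estimates(1, 0.5)
  expect_equal(unname(f$clipped), c(1, 0, 0))
  f2 <- falconer_estimates(0.70, 0.17)
  expect_equal(f2$A, 1.06)
  expect_equal(f2$C, -0.36)
  expect_equal(f2$E, 0.30)
  expect_equal(unname(f2$clipped), c(1, 0, 0.30))
  expect_equal(sum(f2$start), 1)
  expect_equal(unname(f2$start), c(1, 0, 0.30) / 1.30)
})

test_that("the fitted model is deterministic, equivariant, and beats its starts", {
  set.seed(42)
  pairs <- generate_twin_phenotypes(60, 50, 0.5, 0.2, 0.3, mu = 3,
                                    total_var = 4)
  f1 <- fit_ace(pairs)
  f2 <- fit_ace(pairs)
  expect_identical(coef(f1), coef(f2))
  expect_true(f1$converged)
  expect_equal(f1$a2 + f1$c2 + f1$e2, 1)

  # shifting / positively rescaling the phenotype leaves shares unchanged
  resc <- pairs
  resc$value_twin1 <- 2.5 * pairs$value_twin1 - 7
  resc$value_twin2 <- 2.5 * pairs$value_twin2 - 7
  fr <- fit_ace(resc)
  expect_equal(coef(fr), coef(f1), tolerance = 1e-6)
  expect_equal(fr$mu, 2.5 * f1$mu - 7, tolerance = 1e-6)
  expect_equal(fr$total_var, 2.5^2 * f1$total_var, tolerance = 1e-6)

  # maximized log-likelihood is at least the Falconer-start value
  z <- f1$pairs_std
  rmz <- cor(z$value_twin1[z$zygosity == "MZ"],
             z$value_twin2[z$zygosity == "MZ"])
  rdz <- cor(z$value_twin1[z$zygosity == "DZ"],
             z$value_twin2[z$zygosity == "DZ"])
  st <- falconer_estimates(rmz, rdz)$start
  expect_gte(f1$loglik_std, -ace_neg_loglik(c(sqrt(st), 0), z))

  expect_error(fit_ace(pairs[pairs$zygosity == "MZ", ]), "each zygosity")
  flat <- pairs; flat$value_twin1 <- 1; flat$value_twin2 <- 1
  expect_error(fit_ace(flat), "zero variance")
})

test_that("equal MZ/DZ similarity drives the genetic share to zero", {
  set.seed(43)
  pairs <- generate_twin_phenotypes(1500, 1500, 0, 0.45, 0.55)
  f <- fit_ace(pairs)
  expect_lt(f$a2, 0.08)
  expect_equal(f$c2, 0.45, tolerance = 0.08)
})

test_that("fit agrees with the simplex grid search on small datasets", {
  set.seed(44)
  for (i in 1:4) {
    sh <- c(runif(1, 0, 0.6), runif(1, 0, 0.3))
    pairs <- generate_twin_phenotypes(sample(8:20, 1), sample(8:20, 1),
                                      sh[1], sh[2], 1 - sum(sh),
                                      mu = rnorm(1), total_var = runif(1, 0.5, 3))
    f <- fit_ace(pairs)
    g <- ace_grid_search(pairs, step = 0.005)
    expect_lt(abs(f$loglik - g$loglik), 1e-3)
  }
})

test_that("implied model correlations match empirical correlations at large n", {
  set.seed(45)
  pairs <- generate_twin_phenotypes(4000, 4000, 0.5, 0.2, 0.3)
  f <- fit_ace(pairs)
  emp <- function(z) cor(pairs$value_twin1[pairs$zygosity == z],
                         pairs$value_twin2[pairs$zygosity == z])
  expect_equal(f$a2 + f$c2, emp("MZ"), tolerance = 0.05)
  expect_equal(0.5 * f$a2 + f$c2, emp("DZ"), tolerance = 0.05)
})

test_that("profile intervals contain the estimate and clip at the boundary", {
  set.seed(46)
  pairs <- generate_twin_phenotypes(80, 70, 0.5, 0.1, 0.4)
  f <- fit_ace(pairs)
  ci <- confint(f)
  for (p in rownames(ci)) {
    expect_lte(ci[p, "lower"], f[[p]] + 1e-8)
    expect_gte(ci[p, "upper"], f[[p]] - 1e-8)
    expect_gte(ci[p, "lower"], 0)
    expect_lte(ci[p, "upper"], 1)
  }
  # wider confidence level widens the interval
  ci99 <- confint(f, level = 0.99)
  expect_lte(ci99["a2", 1], ci["a2", 1])
  expect_gte(ci99["a2", 2], ci["a2", 2])

  # a share estimated at zero reports a lower bound of exactly 0
  set.seed(47)
  null_pairs <- generate_twin_phenotypes(100, 90, 0, 0.4, 0.6)
  fn <- fit_ace(null_pairs)
  if (fn$a2 < 1e-6) {
    cin <- confint(fn, parm = "a2")
    expect_identical(cin["a2", "lower"], 0)
  }
})

test_that("S3 methods expose the fit coherently", {
  set.seed(48)
  pairs <- generate_twin_phenotypes(40, 40, 0.4, 0.2, 0.4, mu = 1)
  f <- fit_ace(pairs)
  expect_named(coef(f), c("a2", "c2", "e2"))
  expect_s3_class(logLik(f), "logLik")
  expect_equal(attr(logLik(f), "nobs"), 160L)
  expect_output(print(f), "ACE twin model")
  expect_output(print(summary(f, ci = FALSE)), "observed r_MZ")
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_equal(nrow(sims[[1]]), 80)
  res <- residuals(f)
  expect_length(res, 80)
  expect_true(all(res >= 0))
  # squared Mahalanobis residuals are chi-square(2)ish under the model
  expect_equal(mean(res^2), 2, tolerance = 0.5)
})
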