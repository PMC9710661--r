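test_that("Wald label test: null signal, strong signal, invariances", {
  z <- rep(1:2, each = 10)
  # outcomes identical across groups: zero statistic, p = 1
  y0 <- rep(c(1, 2, 3, 4, 5), 4)
  r0 <- linear_wald_test(y0, z)
  expect_lt(r0$statistic, 1e-20)
  expect_equal(r0$p.value, 1)

  set.seed(73)
  z2 <- rep(1:2, each = 50)
  y <- z2 + rnorm(100, sd = 0.1)
  expect_lt(linear_wald_test(y, z2)$p.value, 1e-6)

  # relabeling the groups flips the sign but not the p-value
  ra <- linear_wald_test(y, z2)
  rb <- linear_wald_test(y, 3 - z2)
  expect_equal(ra$p.value, rb$p.value)
  expect_equal(unname(ra$effect), -unname(rb$effect))

  expect_error(linear_wald_test(y, rep(1, 100)),
               class = "markerdens_no_contrast_error")
  expect_error(linear_wald_test(y, z2, C = cbind(z2 == 2, 1 - (z2 == 2))),
               class = "markerdens_rank_deficiency_error")
})

test_that("Wald label test holds its nominal type-I error", {
  set.seed(79)
  z <- rep(1:2, each = 50)
  pvals <- replicate(2000, linear_wald_test(rnorm(100), z)$p.value)
  rate <- mean(pvals < 0.05)
  expect_gte(rate, 0.04)
  expect_lte(rate, 0.06)
})

test_that("Cox label LRT estimates match an independent Breslow Newton fit", {
  set.seed(83)
  n <- 120
  z <- rep(0:1, each = n / 2)
  tm <- rexp(n, rate = 0.2 * exp(0.7 * z))
  cs <- rexp(n, 0.08)
  y <- pmin(tm, cs); ev <- as.integer(tm <= cs)

  fit_surv <- survival::coxph(survival::Surv(y, ev) ~ z, ties = "breslow")
  ord <- order(y)
  grp <- match(y[ord], unique(y[ord]))
  own <- markerdens:::ppl_newton(matrix(z[ord], ncol = 1), ev[ord], grp,
                                 match(unique(grp), grp))
  expect_equal(own$beta, unname(coef(fit_surv)), tolerance = 1e-6)
  expect_equal(own$loglik_part, fit_surv$loglik[2], tolerance = 1e-8)

  r <- coxph_label_lrt(y, ev, z + 1)
  expect_equal(unname(r$effect["HR"]),
               unname(exp(coef(survival::coxph(survival::Surv(y, ev) ~ z)))))
  # relabeling inverts the hazard ratio and keeps the p-value
  r2 <- coxph_label_lrt(y, ev, 2 - z)
  expect_equal(r$p.value, r2$p.value, tolerance = 1e-10)
  expect_equal(unname(r$effect["HR"]), 1 / unname(r2$effect["HR"]),
               tolerance = 1e-10)

  expect_error(coxph_label_lrt(y, rep(0L, n), z + 1),
               class = "markerdens_no_events_error")
})

test_that("LMM variance-component fit agrees with a direct-likelihood oracle", {
  set.seed(89)
  n <- 80
  sim <- simulate_beta_cohort(100, 100, n_shift = n / 2, n_base = n / 2)
  G <- unclass(to_similarity(jsd_matrix(estimate_densities(sim$samples, R = 256))))
  L <- t(chol(G + 1e-8 * diag(n)))
  y <- drop(L %*% rnorm(n)) * sqrt(1.5) + rnorm(n)

  r <- lmm_variance_lrt(y, G)
  X <- matrix(1, n, 1)
  ll_oracle <- oracle_lmm_loglik(y, X, G, r$effect[["sigma2_g"]],
                                 r$effect[["sigma2_e"]])
  expect_equal(r$details$loglik, ll_oracle, tolerance = 1e-6)

  # the profiled optimum cannot be beaten by nearby parameter values
  for (f in c(0.8, 1.25)) {
    expect_lte(oracle_lmm_loglik(y, X, G, f * r$effect[["sigma2_g"]],
                                 r$effect[["sigma2_e"]]),
               r$details$loglik + 1e-8)
  }
  expect_true(r$statistic >= 0)
})

test_that("LMM test handles boundary and degenerate kernels", {
  set.seed(97)
  expect_warning(lmm_variance_lrt(rnorm(30), diag(30)), "diagonal")

  # boundary: p-value is exactly 1 when the variance estimate is 0
  n <- 50
  sim <- simulate_beta_cohort(100, 50, n_shift = 25, n_base = 25)
  G <- unclass(to_similarity(jsd_matrix(estimate_densities(sim$samples, R = 256))))
  hit_boundary <- FALSE
  for (i in 1:20) {
    r <- lmm_variance_lrt(rnorm(n), G)
    expect_gte(r$statistic, 0)
    if (r$effect[["sigma2_g"]] == 0) {
      expect_identical(r$p.value, 1)
      hit_boundary <- TRUE
    }
  }
  expect_true(hit_boundary)

  bad <- matrix(-1, 5, 5); diag(bad) <- 1
  expect_error(lmm_variance_lrt(rnorm(5), bad),
               class = "markerdens_covariance_error")
})

test_that("Kaplan-Meier tables match the hand product-limit computation", {
  # no events: flat curve at 1
  km0 <- kaplan_meier_by_group(c(1, 2, 3), c(0, 0, 0), c(1, 1, 1))
  expect_true(all(km0$table$surv == 1))

  # single group, events at 1, 2, 3
  km1 <- kaplan_meier_by_group(1:3, rep(1, 3), rep(1, 3))
  expect_equal(km1$table$surv[km1$table$n.event == 1], c(2/3, 1/3, 0))

  # interleaved censoring fixture vs the oracle
  tm <- c(1, 2, 2.5, 3, 3.5, 4, 6, 7)
  ev <- c(1, 0, 1, 1, 0, 0, 1, 0)
  km2 <- kaplan_meier_by_group(tm, ev, rep(1, 8))
  oracle <- oracle_product_limit(tm, ev)
  got <- km2$table[km2$table$n.event == 1, c("time", "surv")]
  expect_equal(got$time, oracle$time)
  expect_equal(got$surv, oracle$surv, tolerance = 1e-12)

  # two groups: annotated test is the label LRT
  set.seed(101)
  z <- rep(1:2, each = 20)
  tm2 <- rexp(40, 0.2 * exp(0.5 * (z - 1)))
  km3 <- kaplan_meier_by_group(tm2, rep(1, 40), z)
  expect_s3_class(km3$test, "assoc_test")
  expect_true(all(c("group", "time", "surv") %in% names(km3$table)))
})

test_that("test results serialize to JSON records", {
  z <- rep(1:2, each = 10)
  r <- linear_wald_test(rep(c(1, 2), 10), z)
  path <- withr::local_tempfile(fileext = ".json")
  write_test_results(r, path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(rec$p_value, r$p.value, tolerance = 1e-12)
  expect_equal(rec$statistic, r$statistic, tolerance = 1e-12)
})
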