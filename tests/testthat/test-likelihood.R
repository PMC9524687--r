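test_that("the Gaussian log-likelihood matches a direct summation", {
  ds <- fx_nf("f2")
  p <- fx_params()
  # zero residual at the generating parameters
  expect_equal(log_likelihood(ds, p, init_state = fx_state()), 0)
  # each residual equal to one noise sd: LL = -N/2
  shifted <- ds
  shifted$y <- lapply(ds$y0, function(v) v + 1)
  N <- sum(lengths(ds$y0))
  expect_equal(log_likelihood(shifted, p, init_state = fx_state()),
               -N / 2, tolerance = 1e-10)
  # independent scalar-loop recomputation at perturbed parameters
  th <- p$theta
  th["R_sys"] <- th[["R_sys"]] * 1.05
  p2 <- cv_params(th, p$config)
  ll <- log_likelihood(ds, p2, init_state = fx_state())
  sim <- simulate_model(p2, n_cycles = ds$meta$obs_opts$n_cycles,
                        rtol = ds$meta$obs_opts$rtol,
                        atol = ds$meta$obs_opts$atol,
                        init_state = fx_state())
  acc <- 0
  for (nm in names(ds$y)) {
    ch <- ds$design$channels[[nm]]
    f <- sim$signals[[ch$source]]
    if (grepl("^p_", ch$source)) f <- f * 7.50062
    f <- if (ch$kind == "series") f else
      switch(ch$feature, max = max(f), min = min(f))
    for (i in seq_along(ds$y[[nm]]))
      acc <- acc - 0.5 * (ds$y[[nm]][i] - f[i])^2 / ds$sigma2[[nm]]
  }
  expect_equal(ll, acc, tolerance = 1e-8)
  # crash guard value for an infeasible parameter vector
  th_bad <- p$theta
  th_bad["Am_ref_LV"] <- th_bad[["Am_ref_LV"]] / 12
  th_bad["Vw_LV"] <- th_bad[["Vw_LV"]] * 6
  expect_equal(log_likelihood(ds, cv_params(th_bad, p$config),
                              init_state = fx_state()), -0.5e10)
})

test_that("chi-squared threshold and closed-form intervals are exact", {
  expect_equal(qchisq(0.95, 1), 3.8415, tolerance = 1e-4)
  # symmetric parabola 2 PL = (theta - theta*)^2 / s^2
  s <- 0.07
  theta <- seq(0.5, 1.5, length.out = 41)
  curve <- structure(list(param = "x", theta = theta,
                          PL = 0.5 * (theta - 1)^2 / s^2, PL_min = 0,
                          theta_ref = 1, design = "f0"),
                     class = "cv_profile")
  ci <- confidence_interval(curve, alpha = 0.95)
  half <- s * sqrt(qchisq(0.95, 1))
  expect_equal(ci$lower, 1 - half, tolerance = 1e-3)
  expect_equal(ci$upper, 1 + half, tolerance = 1e-3)
  expect_equal(ci$classification, "identifiable")
  # completely flat profile: no crossing on either side
  flat <- curve
  flat$PL <- rep(0, 41)
  expect_equal(confidence_interval(flat)$classification,
               "structurally non-identifiable")
  expect_equal(confidence_interval(flat)$lower, -Inf)
  # one-sided crossing
  onesided <- curve
  onesided$PL <- ifelse(theta > 1, 0.5 * (theta - 1)^2 / 0.01, 0)
  expect_equal(confidence_interval(onesided)$classification,
               "practically non-identifiable")
})

test_that("profiles on a quadratic likelihood recover the conditional parabola", {
  # analytic 2-parameter Gaussian negative log-likelihood:
  # -LL = 0.5 * (a (x-1)^2 + b (y-2)^2 + 2 c (x-1)(y-2))
  a <- 40; b <- 10; cc <- 15
  nll <- function(x, y) 0.5 * (a * (x - 1)^2 + b * (y - 2)^2 +
                                 2 * cc * (x - 1) * (y - 2))
  # conditional minimum over y at fixed x: quadratic in x with
  # curvature a - c^2/b (the profile parabola)
  xs <- seq(0.6, 1.4, length.out = 9)
  prof <- vapply(xs, function(x)
    optimize(function(y) nll(x, y), c(-5, 9))$objective, numeric(1))
  expect_equal(prof, 0.5 * (a - cc^2 / b) * (xs - 1)^2, tolerance = 1e-6)
})

test_that("model profiles find their minimum at the generating value", {
  ds <- fx_nf("f4")
  pr <- profile_likelihood(ds, "C_pa", c("C_pa", "R_pulm", "R_sys"),
                           fx_params(), grid = 7, maxit = 60,
                           init_state = fx_state())
  expect_equal(pr$PL_min, 0, tolerance = 0.05)
  i_min <- which.min(pr$PL)
  expect_equal(pr$theta[i_min], pr$theta_ref, tolerance = 0.2)
  # PL is bounded below by the global minimum everywhere
  expect_true(all(pr$PL >= pr$PL_min - 1e-8))
  ci <- confidence_interval(pr)
  expect_equal(ci$classification, "identifiable")
  expect_true(ci$lower < pr$theta_ref && ci$upper > pr$theta_ref)
})
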