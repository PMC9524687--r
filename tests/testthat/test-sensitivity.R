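test_that("the Morris step follows the level formula", {
  expect_equal(morris_step(2), 1)
  expect_equal(morris_step(60), 60 / 118)
  expect_equal(morris_step(60), 0.51, tolerance = 0.005)
  expect_equal(morris_step(1e6), 0.5, tolerance = 1e-5)
  expect_warning(morris_step(7), "even")
})

test_that("elementary effects are exact on additive linear models", {
  f <- function(u) c(lin = 3 * u[1] + u[2] - 0.5 * u[3])
  m <- morris_elementary_effects(f, d = 3, K = 12, l = 60, seed = 4)
  expect_equal(unname(m$mu[, 1]), c(3, 1, -0.5), tolerance = 1e-10)
  expect_equal(unname(m$mu_star[, 1]), c(3, 1, 0.5), tolerance = 1e-10)
  expect_equal(unname(m$s2[, 1]), c(0, 0, 0), tolerance = 1e-10)
  expect_equal(unname(m$M[, 1]), c(3, 1, 0.5), tolerance = 1e-8)
  # ranking by M equals ranking by |coefficient|
  expect_equal(order(m$M[, 1], decreasing = TRUE), c(1, 2, 3))
  # determinism
  m2 <- morris_elementary_effects(f, d = 3, K = 12, l = 60, seed = 4)
  expect_identical(m$M, m2$M)
})

test_that("bilinear interactions produce elementary-effect spread", {
  f <- function(u) c(xy = u[1] * u[2])
  m <- morris_elementary_effects(f, d = 2, K = 80, l = 60, seed = 9)
  # EE of u1 equals the local value of u2: mean near 1/2, variance > 0
  expect_gt(m$s2[1, 1], 0.01)
  expect_equal(m$mu_star[1, 1], 0.5, tolerance = 0.15)
  expect_equal(m$mu_star[2, 1], 0.5, tolerance = 0.15)
})

test_that("failed evaluations are salvaged per elementary effect", {
  # fail whenever the first coordinate exceeds 1/2
  f <- function(u) {
    if (u[1] > 0.5) stop("infeasible")
    c(out = u[1] + u[2])
  }
  m <- morris_elementary_effects(f, d = 2, K = 40, l = 60, seed = 2,
                                 max_fail_frac = 0.9)
  expect_gt(m$n_lost, 0)
  expect_equal(m$mu[2, 1], 1, tolerance = 1e-10)  # u2 effect still exact
  # wholesale failure aborts with a diagnostic
  g <- function(u) stop("never works")
  expect_error(morris_elementary_effects(g, d = 2, K = 5, l = 60, seed = 1),
               "aborted")
})

test_that("the below-average-for-all-outputs fixing rule is strict", {
  M <- rbind(a = c(1, 1, 1, 1), b = c(10, 10, 10, 10),
             c = c(1, 10, 10, 10), d = c(4.4, 4.4, 4.4, 4.4))
  fake <- structure(list(M = M), class = "cv_morris")
  fx <- fix_noninfluential(fake)
  # a is below the mean (4.1) everywhere; c only for 1 of 4 outputs
  expect_setequal(fx$fixed, "a")
  expect_setequal(fx$retained, c("b", "c", "d"))
  # all-equal matrix: nothing strictly below the mean, all retained
  Meq <- matrix(2, 3, 4, dimnames = list(c("x", "y", "z"), NULL))
  fx2 <- fix_noninfluential(structure(list(M = Meq), class = "cv_morris"))
  expect_length(fx2$fixed, 0)
  expect_length(fx2$retained, 3)
})

test_that("Fisher assembly and SVD removal handle canonical cases", {
  # orthonormal sensitivities: perfectly conditioned, nothing removed
  S <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  colnames(S) <- letters[1:4]
  F <- fisher_information(S)
  expect_equal(F, t(F))
  expect_equal(cvident:::.cond_F(F), 1, tolerance = 1e-8)
  sel <- svd_subset_reduce(list(d1 = S), cond_max = 1e8)
  expect_length(sel$removed, 0)

  # diagonal case arithmetic
  S2 <- diag(c(1, 2)); colnames(S2) <- c("p1", "p2")
  expect_equal(unname(fisher_information(S2)), diag(c(1, 4)))
  expect_equal(cvident:::.cond_F(fisher_information(S2)), 4)

  # duplicated column: F singular, exactly one of the pair removed
  S3 <- cbind(a = S[, 1], b = S[, 2], b_dup = S[, 2])
  sel3 <- svd_subset_reduce(list(d1 = S3), cond_max = 1e6)
  expect_length(sel3$removed, 1)
  expect_true(sel3$removed %in% c("b", "b_dup"))
  # tie-break prefers the later column in canonical order
  expect_equal(sel3$removed, "b_dup")
  expect_true(all(c("a") %in% sel3$retained))

  # reduction below two parameters aborts
  S4 <- cbind(a = S[, 1], a2 = S[, 1] + 1e-13 * S[, 2])
  expect_error(svd_subset_reduce(list(d1 = S4), cond_max = 1.0001),
               "fewer than 2")
})

test_that("local sensitivities are log-scaled and step-converged", {
  p <- fx_params()
  ls1 <- local_sensitivity(p, c("R_sys", "C_pa"), "f1", step_frac = 0.01,
                           init_state = fx_state())
  expect_equal(dim(ls1$S), c(100L, 2L))
  expect_true(all(is.finite(ls1$S)))
  expect_equal(colnames(ls1$S), c("R_sys", "C_pa"))
  expect_equal(dim(ls1$S_bar), c(1L, 2L))
  expect_equal(unname(ls1$S_bar["p_RV", ]), unname(colSums(ls1$S^2)))
  # Richardson self-check: halving the step changes entries little
  ls2 <- local_sensitivity(p, c("R_sys", "C_pa"), "f1", step_frac = 0.005,
                           init_state = fx_state())
  rel <- max(abs(ls1$S - ls2$S)) / max(abs(ls1$S))
  expect_lt(rel, 0.01)
})
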