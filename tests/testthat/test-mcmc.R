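test_that("DRAM recovers an analytic 2-D Gaussian target", {
  mu <- c(1, -2)
  Sigma <- matrix(c(1, 0.3, 0.3, 0.5), 2)
  Sinv <- solve(Sigma)
  log_post <- function(x) -0.5 * crossprod(x - mu, Sinv %*% (x - mu))[1]
  ch <- dram_sample(log_post, start = c(0, 0), cov0 = diag(2),
                    n_iter = 20000, seed = 12, adapt_interval = 500)
  post <- ch$samples[5001:20000, ]
  est <- colMeans(post)
  # Monte-Carlo standard error from batch means
  nb <- 30
  bm <- apply(post, 2, function(x)
    sd(tapply(x, rep(seq_len(nb), each = length(x) / nb), mean)) / sqrt(nb))
  expect_lt(abs(est[1] - mu[1]), 3 * bm[1])
  expect_lt(abs(est[2] - mu[2]), 3 * bm[2])
  expect_equal(unname(cov(post)), unname(Sigma), tolerance = 0.1)
  expect_gt(ch$acceptance_rate, 0.1)
  # bit-identical under the seed
  ch2 <- dram_sample(log_post, start = c(0, 0), cov0 = diag(2),
                     n_iter = 500, seed = 12)
  ch3 <- dram_sample(log_post, start = c(0, 0), cov0 = diag(2),
                     n_iter = 500, seed = 12)
  expect_identical(ch2$samples, ch3$samples)
})

test_that("detailed balance holds for the first Metropolis stage", {
  # discretized 1-D target: empirical transition frequencies between
  # two states must satisfy pi(i) P(i->j) = pi(j) P(j->i)
  log_post <- function(x) dnorm(x, 0, 1, log = TRUE)
  ch <- dram_sample(log_post, start = 0, cov0 = matrix(1), n_iter = 40000,
                    seed = 3, adapt_interval = 1e9)  # no adaptation
  x <- round(ch$samples[, 1])            # coarse state space
  trans <- table(head(x, -1), tail(x, -1))
  states <- intersect(c("-1", "0", "1"), rownames(trans))
  pi_emp <- table(x)[states]
  f01 <- trans["0", "1"] / pi_emp[["0"]]
  f10 <- trans["1", "0"] / pi_emp[["1"]]
  # flow 0->1 relative to occupancy equals reverse flow (balance)
  expect_equal(f01 * pi_emp[["0"]] / sum(pi_emp),
               f10 * pi_emp[["1"]] / sum(pi_emp), tolerance = 0.15)
})

test_that("bounded priors reject proposals outside their support", {
  p <- fx_params()
  prior <- uniform_prior(p, c("R_sys", "C_pa"), span = 0.5)
  expect_equal(cvident:::.log_prior(prior, prior$lower + 1e-9), 0)
  expect_identical(cvident:::.log_prior(prior, prior$upper * 1.01), -Inf)
  # a chain under a tight box never leaves it
  lp <- function(x) if (all(abs(x) < 0.5)) 0 else -Inf
  ch <- dram_sample(lp, start = c(0, 0), cov0 = diag(2) * 4,
                    n_iter = 3000, seed = 5)
  expect_true(all(abs(ch$samples) < 0.5))
})

test_that("the crash guard penalizes failures without aborting", {
  calls <- 0
  f <- function(th) {
    calls <<- calls + 1
    if (th[1] < 0) stop("model crash")
    sum(th^2)
  }
  g <- crash_guard(f)
  expect_equal(g(c(2, 1)), 5)
  expect_equal(g(c(-1, 0)), 1e10)
  expect_length(attr(g, "log")$failures, 1)
  expect_equal(attr(g, "log")$failures[[1]], c(-1, 0))
  # penalty dwarfs any feasible misfit seen in pilot runs (SSE of a
  # strongly perturbed but feasible parameter set)
  ds <- fx_noisy("f4")
  th <- fx_params()$theta
  th[cv_reference_subset()] <- th[cv_reference_subset()] * 1.10
  r <- cvident:::.residual_vector(ds, cv_params(th, fx_params()$config),
                                  fx_state())
  expect_lt(sum(r^2), 1e8)
  expect_gt(1e10, 100 * sum(r^2))
})

test_that("Gauss-Newton covariance is exact for linear residual models", {
  A <- matrix(c(2, 0, 1, 1, 3, -1), 3, 2)
  b <- c(1, 2, 3)
  resid_fun <- function(th) as.numeric(A %*% th - b)
  cov <- gauss_newton_covariance(resid_fun, c(0.5, 0.5))
  expect_equal(unname(cov), solve(crossprod(A)), tolerance = 1e-6)
  # failing residuals give NULL (caller falls back)
  expect_null(gauss_newton_covariance(function(th) stop("no"), c(1, 2)))
})

test_that("PSRF and MPSRF match hand calculation and limiting behaviour", {
  # two tiny hand-written chains: B/W arithmetic frozen by hand
  c1 <- matrix(c(1, 2, 3)); c2 <- matrix(c(2, 3, 4))
  # W = 1, B = 3 var(c(2,3)) = 1.5, var+ = 2/3 + 0.5 = 7/6
  expect_equal(psrf(list(c1, c2)), sqrt(7 / 6), tolerance = 1e-12)
  expect_equal(mpsrf(list(c1, c2)), sqrt(2 / 3 + (3 / 2) * 0.5),
               tolerance = 1e-12)
  # iid chains from one distribution: PSRF near 1
  set.seed(8)
  chains <- lapply(1:4, function(i) matrix(rnorm(5000), ncol = 1))
  expect_equal(psrf(chains), 1, tolerance = 0.02)
  # an offset chain blows the diagnostic
  chains_bad <- c(chains[1:3], list(chains[[4]] + 50))
  expect_gt(psrf(chains_bad), 5)
  # degenerate: zero within-chain variance
  expect_warning(v <- psrf(list(matrix(rep(1, 10)), matrix(rep(1, 10)))),
                 "degenerate")
  expect_true(is.na(v))
})

test_that("posterior summaries report location, spread and correlation", {
  const <- matrix(rep(2.5, 400), ncol = 2,
                  dimnames = list(NULL, c("a", "b")))
  s <- posterior_summaries(list(const))
  expect_equal(s$median, c(2.5, 2.5))
  expect_equal(s$map, c(2.5, 2.5))
  expect_equal(s$upper - s$lower, c(0, 0))

  set.seed(21)
  z <- rnorm(20000)
  m <- cbind(z1 = z, z2 = 3 * z)   # perfectly correlated pair
  s2 <- posterior_summaries(list(m))
  expect_equal(s2$lower[1], -1.96, tolerance = 0.05)
  expect_equal(s2$upper[1], 1.96, tolerance = 0.05)
  expect_equal(attr(s2, "correlations")["z1", "z2"], 1, tolerance = 1e-12)
})
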