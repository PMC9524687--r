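# minimal hand-built simulation object for biomarker arithmetic
fake_sim <- function(n = 100) {
  tt <- seq(0, 0.11, length.out = n)
  tri <- function(lo, hi) {
    half <- ceiling(n / 2)
    c(seq(hi, lo, length.out = half),
      seq(lo, hi, length.out = n - half + 1)[-1])
  }
  sig <- data.frame(
    time = tt,
    V_RV = tri(25, 50),
    p_RV = rep(2, n),                      # kPa
    p_PA = rep(2, n), p_LA = rep(0.5, n),
    Ls_LV = rep(2, n), Ls_RV = rep(2, n), Ls_S = rep(2, n))
  structure(list(time = tt, signals = sig, period = 0.11),
            class = "cv_sim")
}

test_that("biomarkers follow their defining arithmetic", {
  s <- fake_sim()
  b <- biomarkers(s)
  expect_equal(unname(b["SV_RV"]), 25)
  mpap <- 2 * 7.50062
  mlap <- 0.5 * 7.50062
  expect_equal(unname(b["mean_PA_pressure"]), mpap, tolerance = 1e-10)
  expect_equal(unname(b["Ea_pa"]), (mpap - mlap) / 25, tolerance = 1e-10)
  # end systole = minimum RV volume; p_RV constant 2 kPa here
  expect_equal(unname(b["Ees_RV"]), 2 * 7.50062 / 25, tolerance = 1e-10)
  expect_equal(unname(b["VVC"]), unname(b["Ees_RV"] / b["Ea_pa"]),
               tolerance = 1e-12)
  # ratio identity example
  expect_equal(unname(1.0 / 0.5), 2.0)
})

test_that("biomarkers of a model run match trace arithmetic", {
  sim <- fx_sim()
  b <- biomarkers(sim)
  s <- sim$signals
  expect_equal(unname(b["SV_RV"]), max(s$V_RV) - min(s$V_RV))
  expect_equal(unname(b["mean_PA_pressure"]), mean(s$p_PA) * 7.50062)
  i <- which.min(s$V_RV)
  expect_equal(unname(b["Ees_RV"]), s$p_RV[i] * 7.50062 / s$V_RV[i])
  expect_equal(unname(b["VVC"] * b["Ea_pa"]), unname(b["Ees_RV"]),
               tolerance = 1e-12)
  # plausible normotensive values
  expect_gt(b["VVC"], 0.3); expect_lt(b["VVC"], 10)
})

test_that("engineering strain is zero at onset and tracks length change", {
  s <- fake_sim()
  expect_equal(engineering_strain(s, "LV"), rep(0, 100))
  s$signals$Ls_RV <- seq(2, 1.8, length.out = 100)  # 10% shortening
  st <- engineering_strain(s, "RV")
  expect_equal(st[1], 0)
  expect_equal(st[100], -10, tolerance = 1e-10)
  # mirror-symmetric ventricles: identical LV and RV strain traces
  sym <- simulate_model(fx_symmetric_params(), n_cycles = 20,
                        rtol = 1e-6, atol = 1e-6)
  expect_equal(engineering_strain(sym, "LV"), engineering_strain(sym, "RV"),
               tolerance = 0.25)
})

test_that("posterior-predictive subsampling has the stated shape", {
  fake_chain <- function(seed) {
    set.seed(seed)
    structure(list(post = matrix(rnorm(200 * 3), 200, 3,
                                 dimnames = list(NULL, c("a", "b", "c"))),
                   acceptance_rate = 0.3),
              class = "cv_chain")
  }
  chains12 <- lapply(1:12, fake_chain)
  d <- sample_posterior_predictive(chains12, n_per_chain = 50, seed = 1)
  expect_equal(dim(d), c(600L, 3L))
  # determinism
  d2 <- sample_posterior_predictive(chains12, n_per_chain = 50, seed = 1)
  expect_identical(d, d2)
  # short chains fall back to replacement with a warning
  short1 <- fake_chain(1); short1$post <- short1$post[1:10, , drop = FALSE]
  short <- list(short1, fake_chain(2))
  expect_warning(ds <- sample_posterior_predictive(short, n_per_chain = 50,
                                                   seed = 2),
                 "replacement")
  expect_equal(nrow(ds), 100)
})

test_that("degenerate posteriors give zero-width forecast envelopes", {
  th <- fx_params()$theta[c("R_sys", "C_pa")]
  const_chain <- structure(
    list(post = matrix(rep(th, each = 50), 50, 2,
                       dimnames = list(NULL, names(th))),
         acceptance_rate = 0.2), class = "cv_chain")
  draws <- sample_posterior_predictive(list(const_chain), n_per_chain = 4,
                                       seed = 3)
  fc <- forecast_uq(draws, fx_params(), init_state = fx_state(), seed = 4)
  expect_equal(fc$n_draws, 4)
  expect_lt(max(fc$envelopes$p_LV$sd), 1e-9)
  expect_equal(nrow(fc$biomarkers), 4)
  expect_lt(max(apply(fc$biomarkers, 2, sd)), 1e-9)
  # per-draw coupling identity
  expect_equal(fc$biomarkers[, "VVC"] * fc$biomarkers[, "Ea_pa"],
               fc$biomarkers[, "Ees_RV"], tolerance = 1e-12)
  # summary arithmetic against hand computation
  sm <- summarize_forecast(fc)
  expect_equal(unname(sm$biomarker_summary["median", "SV_RV"]),
               median(fc$biomarkers[, "SV_RV"]))
  expect_equal(sm$max_strain, max(sapply(fc$strain, max)))
})
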