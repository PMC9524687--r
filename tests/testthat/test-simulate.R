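test_that("steady-state simulation conserves volume and is periodic", {
  s <- fx_sim()
  tot <- rowSums(s$signals[paste0("V_", c("LA", "LV", "RA", "RV",
                                          "SA", "SV", "PA", "PV"))])
  V0 <- sum(fx_params()$config$init_volumes)
  expect_lt(max(abs(tot - V0)) / V0, 1e-3)
  expect_lt(s$convergence, 1e-3)
  expect_lt(s$residual_max, 1e-7)
  expect_length(s$time, 100)
  expect_equal(max(s$time) - min(s$time), s$period)
  expect_true(all(s$signals[grep("^V_", names(s$signals))] > 0))
})

test_that("doubling the cycle count barely changes the final cycle", {
  a <- simulate_model(fx_params(), n_cycles = 20, rtol = 1e-6, atol = 1e-6)
  b <- simulate_model(fx_params(), n_cycles = 40, rtol = 1e-6, atol = 1e-6)
  rel <- max(abs(a$signals$p_RV - b$signals$p_RV)) / max(abs(b$signals$p_RV))
  expect_lt(rel, 0.005)
})

test_that("nominal hemodynamics sit in normotensive mouse ranges", {
  s <- fx_sim()$signals
  to_mmhg <- 7.50062
  p_lv <- s$p_LV * to_mmhg
  p_rv <- s$p_RV * to_mmhg
  p_pa <- s$p_PA * to_mmhg
  # RV systolic well below LV systolic
  expect_lt(max(p_rv), max(p_lv) / 2)
  expect_gt(max(p_lv), 80); expect_lt(max(p_lv), 130)
  expect_gt(max(p_rv), 15); expect_lt(max(p_rv), 40)
  expect_gt(mean(p_pa), 10); expect_lt(mean(p_pa), 25)
  sv <- max(s$V_RV) - min(s$V_RV)
  expect_gt(sv, 15); expect_lt(sv, 45)
  expect_gt(min(s$V_LV), 10); expect_lt(max(s$V_LV), 90)
})

test_that("compiled Runge-Kutta agrees with the lsoda cross-check", {
  p <- fx_params()
  a <- simulate_model(p, n_cycles = 3, rtol = 1e-7, atol = 1e-7,
                      method = "rk45")
  b <- simulate_model(p, n_cycles = 3, rtol = 1e-7, atol = 1e-7,
                      method = "lsoda")
  rel <- max(abs(a$signals$p_LV - b$signals$p_LV)) / max(abs(a$signals$p_LV))
  expect_lt(rel, 1e-3)
  relV <- max(abs(a$signals$V_RV - b$signals$V_RV)) / max(a$signals$V_RV)
  expect_lt(relV, 1e-3)
})

test_that("mirror-symmetric ventricles trace identical pressure-volume loops", {
  p <- fx_symmetric_params()
  s <- simulate_model(p, n_cycles = 20, rtol = 1e-6, atol = 1e-6)$signals
  scale_p <- max(abs(s$p_LV))
  expect_lt(max(abs(s$p_LV - s$p_RV)) / scale_p, 0.01)
  expect_lt(max(abs(s$V_LV - s$V_RV)) / max(s$V_LV), 0.01)
  # flat septum throughout the cycle
  expect_lt(max(abs(s$Cm_S)) / max(abs(s$Cm_LV)), 0.02)
})

test_that("infeasible parameter choices raise a classed simulation failure", {
  p <- fx_params()
  th <- p$theta
  th["Am_ref_LV"] <- th[["Am_ref_LV"]] / 12   # wall far too small to fill
  th["Vw_LV"] <- th[["Vw_LV"]] * 6
  expect_error(simulate_model(cv_params(th, p$config), n_cycles = 20,
                              rtol = 1e-5, atol = 1e-5),
               class = "cvident_sim_failure")
})

test_that("simulation results serialize to CSV with a JSON sidecar", {
  s <- fx_sim()
  d <- tempfile()
  paths <- write_simulation(s, d)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[["csv"]], check.names = FALSE)
  expect_equal(nrow(back), 100)
  expect_equal(back$p_LV, s$signals$p_LV, tolerance = 1e-10)
  meta <- jsonlite::read_json(paths[["json"]])
  expect_equal(meta$n_cycles, s$meta$n_cycles)
  expect_equal(meta$params_hash, s$meta$params_hash)
})
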