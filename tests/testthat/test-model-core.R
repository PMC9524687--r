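test_that("mid-wall strain and tension match direct arithmetic", {
  # reference flat wall
  r <- midwall_strain(Am = 100, Am_ref = 100, Cm = 0, V_wall = 500)
  expect_equal(r$eps_f, 0)
  expect_equal(r$z, 0)
  # log identity at zero curvature
  r2 <- midwall_strain(Am = exp(2) * 100, Am_ref = 100, Cm = 0, V_wall = 500)
  expect_equal(r2$eps_f, 1, tolerance = 1e-12)
  # direct evaluation of the strain/curvature law
  r3 <- midwall_strain(Am = 200, Am_ref = 100, Cm = 0.01, V_wall = 500)
  expect_equal(r3$z, 0.0375, tolerance = 1e-12)
  expect_equal(r3$eps_f,
               0.5 * log(2) - 0.0375^2 / 12 - 0.019 * 0.0375^4,
               tolerance = 1e-12)
  expect_equal(r3$eps_f, 0.346456, tolerance = 1e-5)

  expect_equal(midwall_tension(500, 10, 200, 0), 500 * 10 / 400)
  expect_equal(midwall_tension(500, 0, 200, 0.5), 0)
  expect_equal(midwall_tension(500, 10, 200, 0.0375),
               12.5 * (1 + 0.0375^2 / 3 + 0.0375^4 / 5), tolerance = 1e-12)
  expect_equal(midwall_tension(500, 10, 200, 0.0375), 12.5059,
               tolerance = 1e-4)
  expect_error(midwall_strain(-1, 100, 0, 500), "positive")
})

test_that("circuit elements follow the electric analogy and diode law", {
  expect_equal(compartment_pressure(V = 30, V_un = 30, C = 5), 0)
  expect_equal(compartment_pressure(V = 40, V_un = 30, C = 5), 2)
  expect_equal(flow(2, 1, 0.5), 2)
  expect_equal(valve_flow(2, 1, 0.5), 2)
  expect_equal(valve_flow(1, 2, 0.5), 0)
  # monotone, non-negative in the pressure gradient
  dp <- seq(-2, 2, by = 0.25)
  q <- valve_flow(dp + 1, 1, 0.4)
  expect_true(all(q >= 0))
  expect_true(all(diff(q) >= 0))
  expect_error(flow(1, 0, -1), "positive")
})

test_that("sarcomere stress splits into active and passive parts", {
  p <- fx_params()
  th <- p$theta
  # no activation: purely passive
  s0 <- total_stress(2.1, 1.9, 0, p, "ventricular")
  expect_equal(s0$act, 0)
  expect_equal(s0$total, s0$ecm + s0$titin)
  # both passive laws vanish at the passive reference length
  sref <- total_stress(th[["Ls_pas_ref_V"]], 1.9, 0, p, "ventricular")
  expect_equal(sref$ecm, 0, tolerance = 1e-12)
  expect_equal(sref$titin, 0, tolerance = 1e-12)
  expect_equal(sref$total, 0, tolerance = 1e-12)
  # mid-systolic state against an independent R evaluation of the laws
  Ls <- 1.85; Lsc <- 1.70; Gam <- 0.9
  s <- total_stress(Ls, Lsc, Gam, p, "ventricular")
  act <- th[["sigma_act_V"]] * Gam * max(Lsc - th[["Lsc0_V"]], 0) *
    (Ls - Lsc) / th[["Ls_iso_V"]]
  rr <- Ls / th[["Ls_pas_ref_V"]]
  ecm <- th[["sigma_pas_V"]] * (rr^th[["beta_pas_V"]] - rr^-6)
  titin <- 0.01 * th[["sigma_act_V"]] * (rr^th[["k1_V"]] - 1)
  expect_equal(s$act, act, tolerance = 1e-12)
  expect_equal(s$ecm, ecm, tolerance = 1e-12)
  expect_equal(s$titin, titin, tolerance = 1e-12)
  expect_equal(s$total, act + ecm + titin, tolerance = 1e-12)
  expect_error(total_stress(NaN, 1.9, 0, p), "finite")
})

test_that("sarcomere rates reproduce the series and activation laws", {
  p <- fx_params()
  th <- p$theta
  # isometric series element: Ls = Lsc + Ls_iso gives zero velocity
  r <- sarcomere_rates(1.8 + th[["Ls_iso_V"]], 1.8, 0.5, t = 0.01, p)
  expect_equal(unname(r[["dLsc"]]), 0, tolerance = 1e-12)
  # diastolic rest: long after systole, at resting contractility
  rd <- sarcomere_rates(1.96, 1.92, th[["gamma_rest_V"]], t = 0.095, p)
  expect_equal(unname(rd[["dGamma"]]), 0, tolerance = 1e-6)
  # independent R evaluation of both rates at a mid-cycle state
  Ls <- 1.88; Lsc <- 1.80; Gam <- 0.6; t <- 0.02
  rr <- sarcomere_rates(Ls, Lsc, Gam, t, p, "ventricular")
  x <- t / th[["tau_rise_V"]]
  Fr <- if (x < 8) 0.02 * x^3 * (8 - x)^2 * exp(-x) else 0
  Fd <- 0.5 * (1 + tanh((t - th[["tau_sys_V"]]) / th[["tau_decay_V"]]))
  dG <- max(Lsc - th[["Lsc0_V"]], 0) * Fr / th[["tau_rise_V"]] -
    Fd * (Gam - th[["gamma_rest_V"]]) / th[["tau_decay_V"]]
  dL <- ((Ls - Lsc) / th[["Ls_iso_V"]] - 1) * th[["v0_V"]]
  expect_equal(unname(rr[["dGamma"]]), dG, tolerance = 1e-10)
  expect_equal(unname(rr[["dLsc"]]), dL, tolerance = 1e-10)
  # atrial clock: activation rises shortly after the configured offset
  ra <- sarcomere_rates(2.1, 2.0, 0.01, th[["tau_offset_A"]] + 0.01, p,
                        "atrial")
  expect_gt(ra[["dGamma"]], 0)
  # periodic in the cardiac period
  rb <- sarcomere_rates(1.88, 1.80, 0.6, t + p$config$period, p)
  expect_equal(rr, rb, tolerance = 1e-12)
})

test_that("TriSeg equilibrium matches a brute-force residual search", {
  p <- fx_params()
  sol <- triseg_equilibrium(V_LV = 50, V_RV = 55,
                            Lsc = c(1.90, 1.90, 1.88),
                            Gamma = c(0.5, 0.4, 0.45), p)
  expect_true(sol$converged)
  # residuals meet the contract tolerance relative to the tension scale
  expect_lt(sqrt(sol$Rx^2 + sol$Ry^2) / sol$Tscale, 1e-8)
  # independent derivative-free minimization of the residual norm
  pk <- cvident:::.pack_params(p)
  fobj <- function(x) {
    r <- cvident:::cv_triseg_residual(x[1], x[2], 50, 55, c(1.90, 1.90, 1.88),
                            c(0.5, 0.4, 0.45), pk)
    if (!isTRUE(r$converged)) return(1e6)
    v <- sqrt(r$Rx^2 + r$Ry^2) / r$Tscale
    if (is.finite(v)) v else 1e6
  }
  o <- optim(c(sol$VmS * 1.4 + 2, sol$ym * 0.8), fobj,
             control = list(maxit = 4000, reltol = 1e-15))
  expect_lt(o$value, 1e-6)
  expect_equal(o$par[1], sol$VmS, tolerance = 1e-3)
  expect_equal(o$par[2], sol$ym, tolerance = 1e-3)
  expect_error(triseg_equilibrium(-1, 50, rep(1.9, 3), rep(0, 3), p),
               class = "cvident_infeasible")
})

test_that("mirror-symmetric ventricles give a flat septum and equal pressures", {
  p <- fx_symmetric_params()
  sol <- triseg_equilibrium(V_LV = 48, V_RV = 48,
                            Lsc = c(1.9, 1.9, 1.9),
                            Gamma = c(0.3, 0.3, 0.3), p)
  expect_lt(abs(sol$Cm[["S"]]), 1e-6)
  expect_lt(abs(sol$VmS), 1e-4)
  expect_equal(sol$p_LV, sol$p_RV, tolerance = 1e-6)
})

test_that("assembled right-hand side is consistent with its scalar parts", {
  p <- fx_params()
  y <- fx_state()
  r <- assemble_rhs(y, t = 0.03, p)
  dv <- r$dstate[grep("^V_", names(r$dstate))]
  # exact blood-volume conservation
  expect_equal(sum(dv), 0, tolerance = 1e-10)
  # flows recomputed from the reported pressures via the circuit ops
  a <- r$aux
  th <- p$theta
  expect_equal(unname(a[["q_mval"]]),
               valve_flow(a[["p_LA"]], a[["p_LV"]], th[["Rm_val"]]),
               tolerance = 1e-10)
  expect_equal(unname(a[["q_sys"]]),
               flow(a[["p_SA"]], a[["p_SV"]], th[["R_sys"]]),
               tolerance = 1e-10)
  expect_equal(unname(r$dstate[["V_LA"]]),
               unname(a[["q_pv"]] - a[["q_mval"]]), tolerance = 1e-10)
  expect_equal(unname(r$dstate[["V_PA"]]),
               unname(a[["q_pval"]] - a[["q_pulm"]]), tolerance = 1e-10)
  # sarcomere rows match the scalar rate law at the reported lengths
  rs <- sarcomere_rates(a[["Ls_LV"]], y[["Lsc_LV"]], y[["Gamma_LV"]],
                        0.03, p, "ventricular")
  expect_equal(unname(r$dstate[["Lsc_LV"]]), unname(rs[["dLsc"]]),
               tolerance = 1e-10)
  expect_equal(unname(r$dstate[["Gamma_LV"]]), unname(rs[["dGamma"]]),
               tolerance = 1e-10)
  # vascular pressures match the compartment law
  expect_equal(unname(a[["p_SA"]]),
               compartment_pressure(y[["V_SA"]], p$config$V_un[["SA"]],
                                    th[["C_sa"]]), tolerance = 1e-12)

  # all valves shut when every upstream pressure is below downstream
  y2 <- y
  y2["V_SA"] <- 3 * y[["V_SA"]]   # hypertensive arteries close the valves
  y2["V_PA"] <- 3 * y[["V_PA"]]
  y2[c("Gamma_LA", "Gamma_LV", "Gamma_RA", "Gamma_RV", "Gamma_S")] <- 1e-3
  r2 <- assemble_rhs(y2, t = 0.07, p)
  expect_equal(unname(r2$aux[["q_aval"]]), 0)
  expect_equal(unname(r2$aux[["q_pval"]]), 0)
})
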