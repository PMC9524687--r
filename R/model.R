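#' Total sarcomere stress
#'
#' Sum of the active crossbridge stress and the two passive stresses
#' (extracellular matrix and titin). The active component requires the
#' contractile state `(L_sc, Gamma)`; both passive components depend on
#' sarcomere length only and vanish at the passive reference length.
#'
#' @param Ls sarcomere length (um)
#' @param Lsc contractile-element length (um)
#' @param Gamma contractility (dimensionless)
#' @param params `cv_params`
#' @param wall_group `"atrial"` or `"ventricular"`
#' @return list with components `act`, `ecm`, `titin`, `total` (kPa)
#' @export
total_stress <- function(Ls, Lsc, Gamma, params, wall_group = "ventricular") {
  if (!all(is.finite(c(Ls, Lsc, Gamma))) || Ls <= 0 || Lsc <= 0)
    stop("invalid sarcomere state: lengths must be positive and finite")
  grp <- match.arg(wall_group, c("atrial", "ventricular"))
  cv_sarc_stress(Ls, Lsc, Gamma, .pack_params(params),
                 if (grp == "atrial") 0L else 1L)
}

#' Sarcomere state derivatives
#'
#' Time derivatives of the contractile-element length (linear series
#' element) and of contractility, the latter driven by a length-gated
#' rise function and a post-systolic decay toward the resting level.
#' Atrial walls use a clock shifted by the atrial activation delay.
#'
#' @inheritParams total_stress
#' @param t time within the simulation (s)
#' @return named numeric vector `c(dLsc, dGamma)`
#' @export
sarcomere_rates <- function(Ls, Lsc, Gamma, t, params,
                            wall_group = "ventricular") {
  if (!all(is.finite(c(Ls, Lsc, Gamma, t))))
    stop("invalid sarcomere state: non-finite input")
  grp <- match.arg(wall_group, c("atrial", "ventricular"))
  cv_sarc_rates(Ls, Lsc, Gamma, t, .pack_params(params),
                if (grp == "atrial") 0L else 1L)
}

#' Mid-wall natural strain and curvature ratio
#'
#' @param Am current mid-wall area (mm^2)
#' @param Am_ref reference mid-wall area (mm^2)
#' @param Cm mid-wall curvature (1/mm)
#' @param V_wall wall volume (mm^3)
#' @return list with `eps_f` (natural fiber strain) and `z`
#'   (dimensionless curvature ratio)
#' @export
midwall_strain <- function(Am, Am_ref, Cm, V_wall) {
  if (any(Am <= 0) || any(Am_ref <= 0) || any(V_wall <= 0))
    stop("Am, Am_ref and V_wall must be positive")
  z <- 3 * Cm * V_wall / (2 * Am)
  eps_f <- 0.5 * log(Am / Am_ref) - z^2 / 12 - 0.019 * z^4
  list(eps_f = eps_f, z = z)
}

#' Mid-wall tension from wall stress and curvature
#'
#' @param V_wall wall volume (mm^3)
#' @param G_tot total wall stress (kPa)
#' @param Am mid-wall area (mm^2)
#' @param z curvature ratio from [midwall_strain()]
#' @return representative mid-wall tension (kPa mm)
#' @export
midwall_tension <- function(V_wall, G_tot, Am, z) {
  if (any(Am <= 0)) stop("Am must be positive")
  (V_wall * G_tot / (2 * Am)) * (1 + z^2 / 3 + z^4 / 5)
}

#' Pressure of a compliant vascular compartment
#' @param V volume (ul)
#' @param V_un unstressed volume (ul)
#' @param C compliance (ul/kPa)
#' @return pressure (kPa)
#' @export
compartment_pressure <- function(V, V_un, C) {
  if (any(C <= 0)) stop("compliance must be positive")
  (V - V_un) / C
}

#' Flow through a linear resistor
#' @param p_in,p_out upstream and downstream pressures (kPa)
#' @param R resistance (kPa s/ul)
#' @return flow (ul/s)
#' @export
flow <- function(p_in, p_out, R) {
  if (any(R <= 0)) stop("resistance must be positive")
  (p_in - p_out) / R
}

#' Flow through a diode valve
#'
#' Identical to [flow()] when the upstream pressure exceeds the
#' downstream pressure and zero otherwise.
#' @inheritParams flow
#' @return flow (ul/s), non-negative
#' @export
valve_flow <- function(p_in, p_out, R) {
  q <- flow(p_in, p_out, R)
  ifelse(p_in > p_out, q, 0)
}

#' Solve the septal tension balance (TriSeg equilibrium)
#'
#' Finds the septal cap volume and junction radius at which the axial
#' and radial tension components of the LV free wall, RV free wall and
#' septum sum to zero, and derives wall kinematics and cavity pressures
#' from the resolved configuration.
#'
#' @param V_LV,V_RV cavity volumes (ul)
#' @param Lsc,Gamma numeric vectors of length 3 with the contractile
#'   state of the LV, RV and S walls (in that order)
#' @param params `cv_params`
#' @param VmS0,ym0 optional warm-start guesses
#' @param tol residual tolerance relative to the tension scale
#' @param maxit Newton iteration cap
#' @return list with `VmS`, `ym`, residuals, per-wall `Am`, `Cm`,
#'   `eps_f`, `Ls`, `Tm` and cavity pressures `p_LV`, `p_RV`
#' @export
triseg_equilibrium <- function(V_LV, V_RV, Lsc, Gamma, params,
                               VmS0 = NA_real_, ym0 = NA_real_,
                               tol = 1e-8, maxit = 50L) {
  if (!(V_LV > 0) || !(V_RV > 0))
    stop_infeasible("chamber volumes must be positive")
  stopifnot(length(Lsc) == 3, length(Gamma) == 3)
  res <- cv_triseg_solve(V_LV, V_RV, as.numeric(Lsc), as.numeric(Gamma),
                         .pack_params(params), VmS0, ym0, tol, maxit)
  if (!isTRUE(res$converged))
    stop_infeasible("TriSeg tension balance: no root found within budget")
  res
}

stop_infeasible <- function(msg) {
  stop(structure(class = c("cvident_infeasible", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_simfail <- function(msg, diagnostics = NULL) {
  stop(structure(class = c("cvident_sim_failure", "error", "condition"),
                 list(message = msg, call = sys.call(-1),
                      diagnostics = diagnostics)))
}

#' Canonical state names of the 18 differential states
#' @return character vector of length 18
#' @export
cv_state_names <- function() {
  c(paste0(rep(c("Lsc_", "Gamma_"), times = 5),
           rep(c("LA", "LV", "RA", "RV", "S"), each = 2)),
    paste0("V_", c("LA", "LV", "RA", "RV", "SA", "SV", "PA", "PV")))
}

.aux_names <- function() {
  c(paste0("p_", c("LA", "LV", "RA", "RV", "SA", "SV", "PA", "PV")),
    paste0("q_", c("mval", "aval", "sys", "vc", "tval", "pval", "pulm", "pv")),
    as.vector(t(outer(c("LA", "LV", "RA", "RV", "S"),
                      c("eps_f_", "Ls_", "Am_", "Cm_", "Tm_"),
                      function(w, q) paste0(q, w)))),
    "VmS", "ym", "triseg_resid")
}

#' Default initial model state
#'
#' Sarcomere lengths start at their stress-free series configuration,
#' contractility at rest, and volumes at the configured initial
#' distribution of the total stressed blood volume.
#'
#' @param params `cv_params`
#' @return named numeric vector of length 18
#' @export
initial_state <- function(params) {
  params <- .assert_params(params)
  th <- params$theta
  y <- numeric(18)
  names(y) <- cv_state_names()
  for (w in c("LA", "RA")) {
    y[paste0("Lsc_", w)] <- th["Ls_ref_A"] - th["Ls_iso_A"]
    y[paste0("Gamma_", w)] <- th["gamma_rest_A"]
  }
  for (w in c("LV", "RV", "S")) {
    y[paste0("Lsc_", w)] <- th["Ls_ref_V"] - th["Ls_iso_V"]
    y[paste0("Gamma_", w)] <- th["gamma_rest_V"]
  }
  iv <- params$config$init_volumes
  y[paste0("V_", names(iv))] <- iv
  y
}

#' Evaluate the assembled model right-hand side
#'
#' Resolves the nested TriSeg algebraic pair and returns the 18 state
#' derivatives together with all auxiliary quantities (pressures, flows,
#' wall kinematics).
#'
#' @param state named numeric state vector (see [cv_state_names()])
#' @param t time (s)
#' @param params `cv_params`
#' @return list with `dstate` (named derivatives) and `aux`
#'   (named auxiliary outputs)
#' @export
assemble_rhs <- function(state, t, params) {
  stopifnot(length(state) == 18)
  res <- cv_rhs(t, as.numeric(state[cv_state_names()]), .pack_params(params))
  if (!isTRUE(res$ok))
    stop_infeasible("model right-hand side infeasible at the given state")
  list(dstate = setNames(res$dy, cv_state_names()),
       aux = setNames(res$aux, .aux_names()),
       VmS = res$VmS, ym = res$ym)
}

#' Simulate the cardiovascular model to periodic steady state
#'
#' Integrates the 18-state differential-algebraic system for `n_cycles`
#' cardiac cycles and returns the final cycle sampled on a uniform grid,
#' together with cycle-to-cycle convergence and constraint-residual
#' diagnostics.
#'
#' Two integrators are available: the package's adaptive embedded
#' Cash-Karp Runge-Kutta scheme implemented in compiled code (default;
#' fast enough for screening, profiling and MCMC loops) and
#' `deSolve::lsoda`, a variable-step, variable-order stiff-capable
#' solver used as an independent cross-check.
#'
#' @param params `cv_params`
#' @param n_cycles number of cardiac cycles to integrate
#' @param rtol,atol relative and absolute integration tolerances
#' @param n_out number of uniform samples over the final cycle
#' @param init_state optional named initial state (warm start); defaults
#'   to [initial_state()]
#' @param method `"rk45"` (compiled Cash-Karp) or `"lsoda"`
#' @return object of class `cv_sim`: a list with `time` (grid over one
#'   period), `signals` (data frame of pressures, volumes, flows and
#'   wall kinematics over the final cycle), `end_state`, `convergence`
#'   (max relative change in end-cycle compartment volumes),
#'   `residual_max` (worst TriSeg constraint residual on the grid),
#'   `params`, and solver metadata
#' @export
simulate_model <- function(params, n_cycles = 60, rtol = 1e-12, atol = 1e-12,
                           n_out = 100, init_state = NULL, method = "rk45") {
  params <- .assert_params(params)
  method <- match.arg(method, c("rk45", "lsoda"))
  T <- params$config$period
  t_end <- n_cycles * T
  y0 <- if (is.null(init_state)) initial_state(params) else
    as.numeric(init_state[cv_state_names()])
  grid <- seq(t_end - T, t_end, length.out = n_out)
  out_times <- c(t_end - 2 * T, grid)
  pk <- .pack_params(params)

  if (method == "rk45") {
    res <- cv_integrate(pk, as.numeric(y0), out_times, rtol = rtol,
                        atol = atol)
    if (res$status != 0)
      stop_simfail(sprintf(
        "integration failed (status %d) near t = %.5g s", res$status,
        if (is.finite(res$t_fail)) res$t_fail else NA_real_),
        diagnostics = res[c("status", "t_fail", "n_steps", "n_rhs")])
    states <- res$states
    aux <- res$aux
    n_rhs <- res$n_rhs
  } else {
    ws <- c(NA_real_, NA_real_)  # warm start so the root branch is tracked
    rhs_fun <- function(t, y, parms) {
      r <- cv_rhs(t, y, parms, ws[1], ws[2])
      if (!isTRUE(r$ok)) return(list(rep(NaN, 18)))
      ws <<- c(r$VmS, r$ym)
      list(r$dy, r$aux)
    }
    sol <- try(deSolve::lsoda(as.numeric(y0), c(0, out_times), rhs_fun, pk,
                              rtol = rtol, atol = atol, maxsteps = 100000),
               silent = TRUE)
    if (inherits(sol, "try-error") || any(!is.finite(sol[, 2:19])))
      stop_simfail("lsoda integration failed")
    sol <- sol[-1, , drop = FALSE]  # drop the initial-time row
    states <- unname(sol[, 2:19, drop = FALSE])
    aux <- unname(sol[, 20:63, drop = FALSE])
    n_rhs <- NA_real_
  }

  colnames(states) <- cv_state_names()
  colnames(aux) <- .aux_names()
  if (any(!is.finite(states)))
    stop_simfail("integration produced non-finite states")
  vol_cols <- paste0("V_", .compartments)
  v_prev <- states[1, vol_cols]
  v_last <- states[nrow(states), vol_cols]
  convergence <- max(abs(v_last - v_prev) / pmax(abs(v_last), 1))

  keep <- 2:nrow(states)
  sig <- data.frame(time = grid - (t_end - T),
                    states[keep, , drop = FALSE],
                    aux[keep, , drop = FALSE], check.names = FALSE)
  if (any(sig[, vol_cols] < 0))
    stop_simfail("negative compartment volume in output cycle")

  residual_max <- max(sig$triseg_resid)

  structure(list(time = sig$time, signals = sig,
                 end_state = setNames(states[nrow(states), ],
                                      cv_state_names()),
                 convergence = convergence, residual_max = residual_max,
                 params = params, period = T,
                 meta = list(n_cycles = n_cycles, rtol = rtol, atol = atol,
                             n_out = n_out, method = method, n_rhs = n_rhs,
                             params_hash = .params_hash(params))),
            class = "cv_sim")
}

#' @export
print.cv_sim <- function(x, ...) {
  s <- x$signals
  cat("<cv_sim>: final-cycle simulation,", length(x$time), "samples over",
      sprintf("%.4g s\n", x$period))
  cat(sprintf("  p_LV %.1f/%.1f  p_RV %.1f/%.1f mmHg;  V_LV %.1f-%.1f  V_RV %.1f-%.1f ul\n",
              max(s$p_LV) * MMHG_PER_KPA, min(s$p_LV) * MMHG_PER_KPA,
              max(s$p_RV) * MMHG_PER_KPA, min(s$p_RV) * MMHG_PER_KPA,
              min(s$V_LV), max(s$V_LV), min(s$V_RV), max(s$V_RV)))
  cat(sprintf("  cycle convergence %.3g, max constraint residual %.3g\n",
              x$convergence, x$residual_max))
  invisible(x)
}

#' Compute and cache a periodic steady state
#'
#' @param params `cv_params`
#' @param ... passed to [simulate_model()]
#' @return named end-of-cycle state vector
#' @export
steady_state <- function(params, ...) {
  simulate_model(params, ...)$end_state
}

#' Write a simulation result to disk
#'
#' Tidy CSV (one row per time point) plus a JSON metadata sidecar with
#' the parameter hash, tolerances, and convergence diagnostics.
#'
#' @param sim a `cv_sim`
#' @param dir output directory (created if needed)
#' @param stem file stem for the pair of files
#' @return paths of the files written, invisibly
#' @export
write_simulation <- function(sim, dir, stem = "simulation") {
  stopifnot(inherits(sim, "cv_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  js <- file.path(dir, paste0(stem, ".json"))
  utils::write.csv(sim$signals, csv, row.names = FALSE)
  jsonlite::write_json(
    c(sim$meta, list(period = sim$period, convergence = sim$convergence,
                     residual_max = sim$residual_max)),
    js, auto_unbox = TRUE, digits = NA)
  invisible(c(csv = csv, json = js))
}
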