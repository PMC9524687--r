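# residual sum of squares returned for crashed simulations: large
# enough to dwarf any feasible misfit, so such proposals carry
# effectively zero posterior mass
CRASH_SSE <- 1e10

#' Gaussian log-likelihood of a dataset under the model
#'
#' `LL = -1/2 sum_k sum_n (y_n^k - f_k(t_n; theta))^2 / sigma_k^2`,
#' with model outputs converted to observation units. The simulation
#' reuses the observation-simulator settings recorded in the dataset,
#' so the noise-free data are reproduced exactly at the generating
#' parameters.
#'
#' @param dataset a `cv_dataset`
#' @param params `cv_params` at which to evaluate the model
#' @param init_state warm-start state (strongly recommended: pass the
#'   cached steady state of the generating parameters)
#' @param crash the value `-crash/2` is returned when the simulation
#'   fails (the crash guard)
#' @return scalar log-likelihood
#' @export
log_likelihood <- function(dataset, params, init_state = NULL,
                           crash = CRASH_SSE) {
  stopifnot(inherits(dataset, "cv_dataset"))
  opts <- dataset$meta$obs_opts %||% .default_obs_opts()
  sim <- tryCatch(.obs_simulate(.assert_params(params), opts, init_state),
                  error = function(e) NULL)
  if (is.null(sim)) return(-0.5 * crash)
  obs <- extract_observations(sim, dataset$design)
  ll <- 0
  for (nm in names(dataset$y)) {
    r <- dataset$y[[nm]] - obs[[nm]]
    ll <- ll - 0.5 * sum(r^2) / dataset$sigma2[[nm]]
  }
  ll
}

# factory: log-likelihood as a function of the subset parameter vector
.ll_factory <- function(dataset, params_base, subset, init_state,
                        crash = CRASH_SSE) {
  force(dataset); force(params_base); force(subset); force(init_state)
  function(theta_sub) {
    if (any(!is.finite(theta_sub)) || any(theta_sub <= 0))
      return(-0.5 * crash)
    p <- .with_theta(params_base, setNames(theta_sub, subset))
    log_likelihood(dataset, p, init_state = init_state, crash = crash)
  }
}

#' Profile likelihood of one parameter
#'
#' Fixes `param` on a uniform grid around its reference value and
#' minimizes the negative log-likelihood over the remaining subset
#' parameters at every grid point. The optimization is derivative-free
#' (Nelder-Mead in units relative to the reference values) and is
#' warm-started from the neighbouring grid point's optimum, walking
#' outward from the reference value in both directions.
#'
#' @param dataset a `cv_dataset` (noise-free for the identifiability
#'   analysis)
#' @param param name of the profiled parameter
#' @param subset character vector of inferred parameter names
#'   (including `param`)
#' @param params_ref `cv_params` holding the reference (true) values
#' @param grid number of grid points
#' @param span half-width of the profiled range relative to the
#'   reference value (0.5 profiles `[0.5, 1.5] * theta_ref`)
#' @param maxit Nelder-Mead iteration budget per start
#' @param n_starts optimizer starts per grid point (neighbour optimum,
#'   reference values, jittered neighbour)
#' @param init_state warm-start state for the simulator
#' @param crash PL value recorded when every start fails
#' @return object of class `cv_profile`: `theta` (grid), `PL`
#'   (minimized negative log-likelihood), `theta_ref`, `opt` metadata
#' @export
profile_likelihood <- function(dataset, param, subset, params_ref,
                               grid = 21, span = 0.5, maxit = 120,
                               n_starts = 3, init_state = NULL,
                               crash = CRASH_SSE) {
  stopifnot(param %in% subset)
  params_ref <- .assert_params(params_ref)
  free <- setdiff(subset, param)
  th_ref <- params_ref$theta
  if (is.null(init_state))
    init_state <- steady_state(params_ref, n_cycles = 30, rtol = 1e-6,
                               atol = 1e-6)
  grid_vals <- seq(th_ref[param] * (1 - span), th_ref[param] * (1 + span),
                   length.out = grid)
  i_mid <- which.min(abs(grid_vals - th_ref[param]))

  nll_at <- function(fixed_val, x_free_rel, budget) {
    # x_free_rel: free parameters relative to reference
    llf <- .ll_factory(dataset, params_ref, c(param, free), init_state,
                       crash = crash)
    obj <- function(x) -llf(c(fixed_val, x * th_ref[free]))
    if (length(free) == 0) return(list(value = obj(numeric(0)),
                                       par = numeric(0)))
    o <- stats::optim(x_free_rel, obj, method = "Nelder-Mead",
                      control = list(maxit = budget,
                                     reltol = 1e-10))
    list(value = o$value, par = o$par)
  }

  PL <- rep(NA_real_, grid)
  sol <- vector("list", grid)
  ref_val <- NA_real_   # centre-point PL, set below
  run_one <- function(i, warm_rel) {
    starts <- list(warm_rel)
    if (n_starts >= 2) starts <- c(starts, list(rep(1, length(free))))
    if (n_starts >= 3)
      starts <- c(starts, list(warm_rel * exp(stats::rnorm(length(free),
                                                           0, 0.03))))
    best <- list(value = Inf, par = warm_rel)
    for (st in starts) {
      r <- tryCatch(nll_at(grid_vals[i], st, maxit),
                    error = function(e) NULL)
      if (!is.null(r) && is.finite(r$value) && r$value < best$value) best <- r
      # far above the confidence threshold: extra restarts cannot
      # change the classification, stop refining this grid point
      if (is.finite(ref_val) && is.finite(best$value) &&
          best$value > ref_val + 20 && best$value < 0.4 * crash) break
    }
    if (!is.finite(best$value)) best$value <- 0.5 * crash
    best
  }
  # centre point first, then walk outward in both directions
  set.seed(sum(utf8ToInt(param)) + grid)
  ctr <- run_one(i_mid, rep(1, length(free)))
  PL[i_mid] <- ctr$value; sol[[i_mid]] <- ctr$par
  ref_val <- ctr$value
  warm <- ctr$par
  if (i_mid > 1) for (i in (i_mid - 1):1) {
    r <- run_one(i, warm)
    PL[i] <- r$value; sol[[i]] <- r$par
    if (r$value < 0.4 * crash) warm <- r$par
  }
  warm <- ctr$par
  if (i_mid < grid) for (i in (i_mid + 1):grid) {
    r <- run_one(i, warm)
    PL[i] <- r$value; sol[[i]] <- r$par
    if (r$value < 0.4 * crash) warm <- r$par
  }
  PL_min <- min(PL)
  structure(list(param = param, theta = grid_vals, PL = PL,
                 PL_min = PL_min, theta_ref = th_ref[[param]],
                 subset = subset, span = span, grid = grid,
                 design = dataset$design$id,
                 opt = list(maxit = maxit, n_starts = n_starts)),
            class = "cv_profile")
}

#' @export
print.cv_profile <- function(x, ...) {
  cat(sprintf("<cv_profile> %s over [%.3g, %.3g] (design %s): min PL %.3g\n",
              x$param, min(x$theta), max(x$theta), x$design, x$PL_min))
  invisible(x)
}

#' Profile-likelihood confidence interval and identifiability class
#'
#' Thresholds the profile at `2 PL = 2 PL_min + q` with `q` the
#' chi-squared(1) quantile at level `alpha`; interval bounds are located
#' by linear interpolation in `2 PL`. A profile that never crosses the
#' threshold on either side of its minimum within the profiled range is
#' classified structurally non-identifiable, a single-sided crossing is
#' practically non-identifiable, and a two-sided crossing identifiable.
#'
#' @param curve a `cv_profile`
#' @param alpha confidence level
#' @return list with `lower`, `upper` (possibly infinite),
#'   `threshold`, `classification`
#' @export
confidence_interval <- function(curve, alpha = 0.95) {
  stopifnot(inherits(curve, "cv_profile"))
  q <- stats::qchisq(alpha, df = 1)
  two_pl <- 2 * (curve$PL - curve$PL_min)
  thr <- q
  if (any(two_pl < -1e-6))
    stop("inconsistent profile: PL below its recorded minimum")
  i_min <- which.min(curve$PL)
  cross <- function(idx) {
    # first threshold crossing walking away from the minimum
    for (k in seq_along(idx)[-1]) {
      a <- idx[k - 1]; b <- idx[k]
      if (two_pl[a] <= thr && two_pl[b] > thr) {
        f <- (thr - two_pl[a]) / (two_pl[b] - two_pl[a])
        return(curve$theta[a] + f * (curve$theta[b] - curve$theta[a]))
      }
    }
    NA_real_
  }
  lower <- if (i_min > 1) cross(seq(i_min, 1)) else NA_real_
  upper <- if (i_min < length(two_pl)) cross(seq(i_min, length(two_pl)))
           else NA_real_
  n_crossed <- sum(!is.na(c(lower, upper)))
  classification <- c("structurally non-identifiable",
                      "practically non-identifiable",
                      "identifiable")[n_crossed + 1]
  list(lower = if (is.na(lower)) -Inf else lower,
       upper = if (is.na(upper)) Inf else upper,
       threshold = thr, alpha = alpha, classification = classification,
       param = curve$param, design = curve$design)
}

#' Profile all subset parameters of a design
#'
#' @inheritParams profile_likelihood
#' @param alpha confidence level for the interval/classification
#' @param params character vector of parameters to profile (default:
#'   the whole subset)
#' @return object of class `cv_profiles`: list of curves, data frame of
#'   intervals and classifications
#' @export
profile_all <- function(dataset, subset, params_ref, params = subset,
                        grid = 21, span = 0.5, alpha = 0.95, maxit = 120,
                        n_starts = 3, init_state = NULL) {
  params_ref <- .assert_params(params_ref)
  if (is.null(init_state))
    init_state <- steady_state(params_ref, n_cycles = 30, rtol = 1e-6,
                               atol = 1e-6)
  curves <- lapply(params, function(pn)
    profile_likelihood(dataset, pn, subset, params_ref, grid = grid,
                       span = span, maxit = maxit, n_starts = n_starts,
                       init_state = init_state))
  names(curves) <- params
  cis <- lapply(curves, confidence_interval, alpha = alpha)
  tab <- do.call(rbind, lapply(cis, function(ci)
    data.frame(param = ci$param, design = ci$design, lower = ci$lower,
               upper = ci$upper, classification = ci$classification)))
  rownames(tab) <- NULL
  structure(list(curves = curves, intervals = tab, alpha = alpha,
                 design = dataset$design$id),
            class = "cv_profiles")
}

#' @export
print.cv_profiles <- function(x, ...) {
  cat("<cv_profiles> design", x$design, "\n")
  print(x$intervals)
  invisible(x)
}
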