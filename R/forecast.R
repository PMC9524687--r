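#' Subsample posterior draws from multiple chains
#'
#' Uniform without-replacement subsampling of post-burn-in iterations,
#' per chain, agglomerated into one draw matrix (e.g., 12 chains x 50
#' draws = 600 realizations).
#'
#' @param chains list of `cv_chain`
#' @param n_per_chain draws taken from each chain
#' @param seed RNG seed
#' @return matrix of parameter draws (rows = draws)
#' @export
sample_posterior_predictive <- function(chains, n_per_chain = 50, seed = 1L) {
  set.seed(seed)
  draws <- lapply(chains, function(ch) {
    m <- if (inherits(ch, "cv_chain")) ch$post %||% ch$samples else
      as.matrix(ch)
    if (nrow(m) < n_per_chain) {
      warning("chain shorter than n_per_chain: sampling with replacement")
      m[sample.int(nrow(m), n_per_chain, replace = TRUE), , drop = FALSE]
    } else {
      m[sample.int(nrow(m), n_per_chain), , drop = FALSE]
    }
  })
  do.call(rbind, draws)
}

#' Hemodynamic biomarkers of a simulated cycle
#'
#' Derives the five pulmonary-hypertension biomarkers from a final-cycle
#' simulation: mean pulmonary artery pressure (mmHg), RV stroke volume
#' `SV_RV = max V_RV - min V_RV` (ul), pulmonary arterial elastance
#' `Ea_pa = (mean p_PA - mean p_LA)/SV_RV` (mmHg/ul), RV end-systolic
#' elastance `Ees_RV = p_RV/V_RV` at the time of minimum RV volume
#' (mmHg/ul), and ventricular-vascular coupling `VVC = Ees_RV/Ea_pa`.
#'
#' @param sim a `cv_sim`
#' @return named numeric vector of the five biomarkers
#' @export
biomarkers <- function(sim) {
  stopifnot(inherits(sim, "cv_sim"))
  s <- sim$signals
  sv <- max(s$V_RV) - min(s$V_RV)
  if (sv <= 0) stop("zero RV stroke volume: elastances undefined")
  mpap <- mean(s$p_PA) * MMHG_PER_KPA
  mlap <- mean(s$p_LA) * MMHG_PER_KPA
  ea <- (mpap - mlap) / sv
  i_es <- which.min(s$V_RV)
  ees <- s$p_RV[i_es] * MMHG_PER_KPA / s$V_RV[i_es]
  c(mean_PA_pressure = mpap, SV_RV = sv, Ea_pa = ea, Ees_RV = ees,
    VVC = ees / ea)
}

#' Engineering strain of a ventricular wall
#'
#' Percent length change of the wall's sarcomeres relative to the cycle
#' onset (the onset of ventricular activation).
#'
#' @param sim a `cv_sim`
#' @param wall `"LV"`, `"RV"` or `"S"`
#' @return numeric strain trace (%), same length as the grid
#' @export
engineering_strain <- function(sim, wall = c("LV", "RV", "S")) {
  wall <- match.arg(wall)
  ls <- sim$signals[[paste0("Ls_", wall)]]
  (ls - ls[1]) / ls[1] * 100
}

#' Posterior-predictive forecast
#'
#' Simulates every posterior draw through the model and aggregates
#' pointwise mean/standard-deviation envelopes of the chamber pressures
#' and volumes, per-wall engineering-strain traces, and samples of the
#' five hemodynamic biomarkers. Failed draws are replaced by resampling
#' from the chains (up to 5% of the draw count; beyond that they are
#' dropped with a warning).
#'
#' @param draws matrix of subset parameter draws (named columns), from
#'   [sample_posterior_predictive()]
#' @param params_ref `cv_params` carrying the fixed parameters
#' @param chains optional chain list used to resample replacements for
#'   failed draws
#' @param obs_opts simulator settings (defaults to the observation
#'   simulator)
#' @param init_state warm-start state
#' @param signals signals to envelope
#' @param seed RNG seed for resampling
#' @return object of class `cv_forecast`: `envelopes` (per signal:
#'   time, mean, sd), `strain` (per wall: draws x time), `biomarkers`
#'   (draws x 5), `n_failed`
#' @export
forecast_uq <- function(draws, params_ref, chains = NULL, obs_opts = NULL,
                        init_state = NULL, seed = 1L,
                        signals = c("p_LA", "p_LV", "p_RA", "p_RV",
                                    "V_LA", "V_LV", "V_RA", "V_RV")) {
  params_ref <- .assert_params(params_ref)
  opts <- utils::modifyList(.default_obs_opts(), obs_opts %||% list())
  if (is.null(init_state))
    init_state <- steady_state(params_ref, n_cycles = 30, rtol = 1e-6,
                               atol = 1e-6)
  subset <- colnames(draws)
  stopifnot(!is.null(subset))
  simulate_draw <- function(th) {
    p <- .with_theta(params_ref, setNames(th, subset))
    tryCatch(.obs_simulate(p, opts, init_state), error = function(e) NULL)
  }
  set.seed(seed)
  pool <- if (!is.null(chains))
    do.call(rbind, lapply(chains, function(ch) ch$post)) else NULL
  sims <- vector("list", nrow(draws))
  n_failed <- 0L
  for (i in seq_len(nrow(draws))) {
    s <- simulate_draw(draws[i, ])
    tries <- 0L
    while (is.null(s) && !is.null(pool) && tries < 5L) {
      n_failed <- n_failed + 1L
      repl <- pool[sample.int(nrow(pool), 1), ]
      draws[i, ] <- repl
      s <- simulate_draw(repl)
      tries <- tries + 1L
    }
    sims[[i]] <- s
  }
  ok <- !vapply(sims, is.null, TRUE)
  if (n_failed > 0.05 * nrow(draws) || any(!ok))
    warning(sprintf("%d forecast draws failed (%d unrecovered)",
                    n_failed, sum(!ok)))
  sims <- sims[ok]
  if (!length(sims)) stop("no forecast draw simulated successfully")
  tgrid <- sims[[1]]$time
  env <- lapply(signals, function(sg) {
    m <- vapply(sims, function(s) .obs_units(s$signals[[sg]], sg),
                numeric(length(tgrid)))
    data.frame(time = tgrid, mean = rowMeans(m),
               sd = apply(m, 1, stats::sd))
  })
  names(env) <- signals
  strain <- lapply(c("LV", "RV", "S"), function(w)
    t(vapply(sims, engineering_strain, numeric(length(tgrid)), wall = w)))
  names(strain) <- c("LV", "RV", "S")
  bio <- t(vapply(sims, biomarkers, numeric(5)))
  structure(list(envelopes = env, strain = strain, biomarkers = bio,
                 time = tgrid, n_draws = length(sims), n_failed = n_failed,
                 draws = draws[ok, , drop = FALSE]),
            class = "cv_forecast")
}

#' @export
print.cv_forecast <- function(x, ...) {
  cat(sprintf("<cv_forecast> %d posterior draws (%d failures recovered)\n",
              x$n_draws, x$n_failed))
  b <- round(apply(x$biomarkers, 2, stats::median), 3)
  cat("  median biomarkers:",
      paste(names(b), b, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a forecast against a reference simulation
#'
#' @param forecast a `cv_forecast`
#' @param truth_sim optional `cv_sim` at the generating parameters;
#'   when given, per-signal flags record whether the truth trace lies
#'   within mean +/- 2 sd everywhere
#' @return list with `biomarker_summary` (median and 95% interval per
#'   biomarker), `max_strain` (max engineering strain over walls,
#'   draws, time), `coverage` (per-signal truth-in-envelope fraction,
#'   if truth supplied)
#' @export
summarize_forecast <- function(forecast, truth_sim = NULL) {
  stopifnot(inherits(forecast, "cv_forecast"))
  bs <- apply(forecast$biomarkers, 2, function(x)
    c(median = stats::median(x), lower = stats::quantile(x, 0.025,
                                                         names = FALSE),
      upper = stats::quantile(x, 0.975, names = FALSE)))
  max_strain <- max(vapply(forecast$strain, max, numeric(1)))
  cov <- NULL
  if (!is.null(truth_sim)) {
    cov <- vapply(names(forecast$envelopes), function(sg) {
      e <- forecast$envelopes[[sg]]
      tr <- .obs_units(truth_sim$signals[[sg]], sg)
      mean(tr >= e$mean - 2 * e$sd & tr <= e$mean + 2 * e$sd)
    }, numeric(1))
  }
  list(biomarker_summary = bs, max_strain = max_strain, coverage = cov)
}
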