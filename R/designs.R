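#' Experimental designs for ventricular measurement protocols
#'
#' Four nested measurement protocols are studied:
#' \describe{
#'   \item{f1}{dynamic RV pressure only}
#'   \item{f2}{dynamic RV pressure and volume}
#'   \item{f3}{f2 plus systolic/diastolic LV pressure and volume scalars
#'     (echocardiography-style point measures)}
#'   \item{f4}{dynamic pressure and volume in both ventricles}
#' }
#' Pressure channels are observed in mmHg, volume channels in ul.
#'
#' @param id one of `"f1"`, `"f2"`, `"f3"`, `"f4"`
#' @param sigma_p,sigma_V noise standard deviations for pressure (mmHg)
#'   and volume (ul) channels
#' @return object of class `cv_design`
#' @export
experimental_design <- function(id = c("f1", "f2", "f3", "f4"),
                                sigma_p = 1, sigma_V = 1) {
  id <- match.arg(id)
  stopifnot(sigma_p > 0, sigma_V > 0)
  ser <- function(sig) list(name = sig, kind = "series", source = sig,
                            unit = if (grepl("^p_", sig)) "mmHg" else "ul",
                            sigma = if (grepl("^p_", sig)) sigma_p else sigma_V)
  sca <- function(nm, sig, feat) list(name = nm, kind = "scalar", source = sig,
                                      feature = feat,
                                      unit = if (grepl("^p_", sig)) "mmHg" else "ul",
                                      sigma = if (grepl("^p_", sig)) sigma_p else sigma_V)
  channels <- switch(id,
    f1 = list(ser("p_RV")),
    f2 = list(ser("p_RV"), ser("V_RV")),
    f3 = list(ser("p_RV"), ser("V_RV"),
              sca("p_LV_sys", "p_LV", "max"), sca("p_LV_dias", "p_LV", "min"),
              sca("V_LV_dias", "V_LV", "max"), sca("V_LV_sys", "V_LV", "min")),
    f4 = list(ser("p_RV"), ser("V_RV"), ser("p_LV"), ser("V_LV")))
  names(channels) <- vapply(channels, `[[`, "", "name")
  structure(list(id = id, channels = channels,
                 sigma_p = sigma_p, sigma_V = sigma_V),
            class = "cv_design")
}

#' @export
print.cv_design <- function(x, ...) {
  cat("<cv_design>", x$id, "-", length(x$channels), "channels:",
      paste(names(x$channels), collapse = ", "), "\n")
  invisible(x)
}

# convert one model signal (kPa / ul) to observation units
.obs_units <- function(values, source) {
  if (grepl("^p_", source)) values * MMHG_PER_KPA else values
}

#' Extract the noise-free observation vector of a design
#'
#' Time-series channels are the full final-cycle grid; the f3 scalars
#' are the systolic (max) and diastolic (min) LV pressure and the
#' end-diastolic (max) and end-systolic (min) LV volume.
#'
#' @param sim a `cv_sim` covering one full cycle
#' @param design a `cv_design`
#' @return named list of numeric vectors, one per channel, in
#'   observation units (mmHg / ul)
#' @export
extract_observations <- function(sim, design) {
  stopifnot(inherits(sim, "cv_sim"), inherits(design, "cv_design"))
  lapply(design$channels, function(ch) {
    x <- sim$signals[[ch$source]]
    if (is.null(x)) stop("simulation lacks signal ", ch$source)
    x <- .obs_units(x, ch$source)
    if (ch$kind == "series") x
    else switch(ch$feature, max = max(x), min = min(x))
  })
}

#' Corrupt noise-free observations with white Gaussian noise
#'
#' Adds independent zero-mean Gaussian noise per sample; pressure
#' channels use variance `sigma_p^2` (mmHg^2), volume channels
#' `sigma_V^2` (ul^2). Deterministic under `seed`.
#'
#' @param observations named list from [extract_observations()]
#' @param design the `cv_design` the observations came from
#' @param seed integer RNG seed
#' @param times time grid of the series channels (s), stored for
#'   bookkeeping
#' @param meta optional list of provenance fields (truth hash,
#'   simulator settings)
#' @return object of class `cv_dataset` with fields `design`, `y`
#'   (noisy), `y0` (noise-free), `sigma2` (per-channel noise variance),
#'   `times`, `seed`, `meta`
#' @export
corrupt <- function(observations, design, seed, times = NULL, meta = list()) {
  stopifnot(inherits(design, "cv_design"))
  set.seed(seed)
  y <- lapply(names(design$channels), function(nm) {
    ch <- design$channels[[nm]]
    observations[[nm]] + stats::rnorm(length(observations[[nm]]),
                                      sd = ch$sigma)
  })
  names(y) <- names(design$channels)
  sigma2 <- vapply(design$channels, function(ch) ch$sigma^2, numeric(1))
  structure(list(design = design, y = y, y0 = observations,
                 sigma2 = sigma2, times = times, seed = seed, meta = meta),
            class = "cv_dataset")
}

#' @export
print.cv_dataset <- function(x, ...) {
  n <- sum(lengths(x$y))
  cat(sprintf("<cv_dataset> design %s: %d observations in %d channels (seed %s)\n",
              x$design$id, n, length(x$y),
              if (is.null(x$seed)) "none" else x$seed))
  invisible(x)
}

# default simulator settings for the observation model: short
# warm-started runs shared verbatim between data generation and
# likelihood evaluation, so solver transients cancel at the truth
.default_obs_opts <- function() {
  list(n_cycles = 5, rtol = 2e-4, atol = 2e-4, n_out = 100)
}

# simulate the observation model at given parameters
.obs_simulate <- function(params, opts, init_state) {
  simulate_model(params, n_cycles = opts$n_cycles, rtol = opts$rtol,
                 atol = opts$atol, n_out = opts$n_out,
                 init_state = init_state)
}

#' Generate the synthetic study datasets for all designs
#'
#' Runs one simulation at the data-generating ("true") parameters and
#' derives the (optionally noise-corrupted) observation vectors of every
#' requested design from that shared truth.
#'
#' @param params_true `cv_params` treated as ground truth
#' @param designs character vector of design ids
#' @param seed integer seed for the noise; per-design seeds are derived
#'   deterministically
#' @param noisy logical; `FALSE` returns noise-free datasets
#' @param sigma_p,sigma_V per-source noise standard deviations
#' @param obs_opts observation-simulator settings (see Details);
#'   defaults to the package's short warm-started configuration
#' @param init_state optional steady state to warm-start from; computed
#'   from `params_true` when missing
#' @return named list of `cv_dataset` objects
#' @details The observation simulator integrates a fixed number of
#' warm-started cycles at moderate tolerance and is recorded in each
#' dataset's metadata; likelihood evaluations reuse the identical
#' settings so that the model reproduces the noise-free data exactly at
#' the true parameters.
#' @export
generate_study_data <- function(params_true, designs = c("f1", "f2", "f3", "f4"),
                                seed = 1L, noisy = TRUE,
                                sigma_p = 1, sigma_V = 1,
                                obs_opts = NULL, init_state = NULL) {
  params_true <- .assert_params(params_true)
  opts <- utils::modifyList(.default_obs_opts(), obs_opts %||% list())
  if (is.null(init_state))
    init_state <- steady_state(params_true, n_cycles = 30,
                               rtol = 1e-6, atol = 1e-6)
  sim <- .obs_simulate(params_true, opts, init_state)
  out <- lapply(seq_along(designs), function(i) {
    d <- experimental_design(designs[i], sigma_p = sigma_p, sigma_V = sigma_V)
    obs <- extract_observations(sim, d)
    meta <- list(truth_hash = .params_hash(params_true), obs_opts = opts,
                 noisy = noisy)
    if (noisy) {
      corrupt(obs, d, seed = seed + 1000L * i, times = sim$time, meta = meta)
    } else {
      ds <- corrupt(obs, d, seed = seed + 1000L * i, times = sim$time,
                    meta = meta)
      ds$y <- ds$y0
      ds
    }
  })
  names(out) <- designs
  out
}

#' Write a dataset to disk (CSV per channel + JSON sidecar)
#'
#' @param dataset a `cv_dataset`
#' @param dir output directory
#' @return paths written, invisibly
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (nm in names(dataset$y)) {
    ch <- dataset$design$channels[[nm]]
    df <- if (ch$kind == "series") {
      data.frame(time = dataset$times %||% seq_along(dataset$y[[nm]]),
                 value = dataset$y[[nm]], noise_free = dataset$y0[[nm]])
    } else {
      data.frame(time = NA_real_, value = dataset$y[[nm]],
                 noise_free = dataset$y0[[nm]])
    }
    f <- file.path(dir, paste0(dataset$design$id, "_", nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  side <- file.path(dir, paste0(dataset$design$id, "_meta.json"))
  jsonlite::write_json(
    list(design = dataset$design$id, seed = dataset$seed,
         sigma2 = as.list(dataset$sigma2), meta = dataset$meta,
         channels = names(dataset$y)),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory containing the files
#' @param id design id to read
#' @return a `cv_dataset`
#' @export
read_dataset <- function(dir, id) {
  side <- jsonlite::read_json(file.path(dir, paste0(id, "_meta.json")),
                              simplifyVector = TRUE)
  design <- experimental_design(id)
  y <- list(); y0 <- list(); times <- NULL
  for (nm in side$channels) {
    df <- utils::read.csv(file.path(dir, paste0(id, "_", nm, ".csv")))
    y[[nm]] <- df$value
    y0[[nm]] <- df$noise_free
    if (design$channels[[nm]]$kind == "series") times <- df$time
  }
  structure(list(design = design, y = y, y0 = y0,
                 sigma2 = unlist(side$sigma2), times = times,
                 seed = side$seed, meta = side$meta),
            class = "cv_dataset")
}
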