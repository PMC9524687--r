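#' Study configuration
#'
#' Bundles every stage's settings for the end-to-end identifiability
#' study. Two scale presets are provided: `"desk"` exercises every code
#' path at small problem sizes, `"paper"` uses the full-scale settings
#' (100 Morris trajectories, 21-point profiles, 12 chains of 50,000
#' iterations, 50 forecast draws per chain).
#'
#' @param scale `"desk"` or `"paper"`
#' @param params_file path to the parameter YAML (default: shipped
#'   nominal mouse file)
#' @param designs design ids to run
#' @param seed master seed; stage seeds are derived deterministically
#' @param ... named overrides of individual fields
#' @return object of class `cv_config`
#' @export
study_config <- function(scale = c("desk", "paper"), params_file = NULL,
                         designs = c("f1", "f2", "f3", "f4"), seed = 1L,
                         ...) {
  scale <- match.arg(scale)
  base <- if (scale == "desk") {
    list(morris_K = 20, morris_l = 60, morris_span = 0.25,
         cond_max = 1e8, pl_grid = 11, pl_alpha = 0.95, pl_maxit = 50,
         mcmc_chains = 3, mcmc_iter = 1500, mcmc_burn = 400,
         n_starts = 3, n_restarts = 4, n_hops = 6,
         forecast_per_chain = 34, sens_opts = NULL,
         subset = NULL)
  } else {
    list(morris_K = 100, morris_l = 60, morris_span = 0.25,
         cond_max = 1e8, pl_grid = 21, pl_alpha = 0.95, pl_maxit = 250,
         mcmc_chains = 12, mcmc_iter = 50000, mcmc_burn = 10000,
         n_starts = 12, n_restarts = 5, n_hops = 20,
         forecast_per_chain = 50, sens_opts = NULL,
         subset = NULL)
  }
  cfg <- utils::modifyList(base, list(...))
  cfg$scale <- scale
  cfg$designs <- designs
  cfg$seed <- as.integer(seed)
  cfg$params_file <- params_file %||%
    system.file("extdata", "nominal_mouse.yaml", package = "cvident")
  structure(cfg, class = "cv_config")
}

#' @export
print.cv_config <- function(x, ...) {
  cat("<cv_config>", x$scale, "preset, designs:",
      paste(x$designs, collapse = ", "), "- seed", x$seed, "\n")
  invisible(x)
}

#' Run the end-to-end identifiability study
#'
#' Executes the full workflow: synthetic-data generation, Morris
#' screening and parameter fixing, local-sensitivity/SVD subset
#' reduction, profile-likelihood classification, DRAM inference, and
#' posterior-predictive forecasting. A stage failure marks the stage in
#' the report and skips downstream stages.
#'
#' @param config a `cv_config`
#' @param out_dir optional directory for artifacts (datasets, CSV/JSON
#'   outputs); nothing is written when `NULL`
#' @return a `cv_report` list with per-stage results and counts
#' @export
run_study <- function(config = study_config(), out_dir = NULL) {
  stopifnot(inherits(config, "cv_config"))
  report <- list(config = unclass(config), stages = list())
  t_all <- Sys.time()
  params <- load_params(config$params_file)
  truth_state <- steady_state(params, n_cycles = 30, rtol = 1e-6,
                              atol = 1e-6)

  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) e)
    elapsed <- as.numeric(Sys.time() - t0, units = "secs")
    ok <- !inherits(res, "error")
    report$stages[[name]] <<- list(
      ok = ok, seconds = elapsed,
      error = if (!ok) conditionMessage(res) else NULL)
    message(sprintf("[%s] %s (%.1f s)", name,
                    if (ok) "done" else paste("FAILED:",
                                              conditionMessage(res)),
                    elapsed))
    if (!ok) NULL else res
  }

  datasets <- stage("generate_data", generate_study_data(
    params, designs = config$designs, seed = config$seed,
    init_state = truth_state))
  datasets_nf <- stage("generate_noisefree", generate_study_data(
    params, designs = config$designs, seed = config$seed, noisy = FALSE,
    init_state = truth_state))

  selection <- stage("subset_selection", subset_selection(
    params, K = config$morris_K, l = config$morris_l,
    seed = config$seed + 1L, morris_span = config$morris_span,
    designs = config$designs, cond_max = config$cond_max,
    obs_opts = config$sens_opts))
  if (is.null(selection)) {
    report$elapsed <- as.numeric(Sys.time() - t_all, units = "secs")
    return(structure(report, class = "cv_report"))
  }
  subset <- config$subset %||% selection$final
  report$counts <- selection$counts

  profiles <- stage("profile_likelihood", {
    out <- lapply(config$designs, function(d)
      profile_all(datasets_nf[[d]], subset, params,
                  grid = config$pl_grid, alpha = config$pl_alpha,
                  maxit = config$pl_maxit, init_state = truth_state))
    names(out) <- config$designs
    out
  })
  if (!is.null(profiles))
    report$classifications <- do.call(rbind, lapply(profiles, `[[`,
                                                    "intervals"))

  mcmc <- stage("mcmc", {
    out <- lapply(config$designs, function(d) {
      starts <- initialize_starts(datasets[[d]], subset, params,
                                  n_starts = config$n_starts,
                                  n_restarts = config$n_restarts,
                                  n_hops = config$n_hops,
                                  seed = config$seed + 7L,
                                  init_state = truth_state)
      chains <- lapply(seq_len(config$mcmc_chains), function(k)
        run_dram(datasets[[d]], subset, params,
                 start = starts[[((k - 1) %% length(starts)) + 1]],
                 n_iter = config$mcmc_iter, burn_in = config$mcmc_burn,
                 seed = config$seed + 100L * k,
                 init_state = truth_state))
      chains
    })
    names(out) <- config$designs
    out
  })
  if (!is.null(mcmc)) {
    report$convergence <- lapply(mcmc, convergence_report)
    report$posteriors <- lapply(mcmc, posterior_summaries,
                                prior = uniform_prior(params, subset))
  }

  forecasts <- stage("forecast", {
    out <- lapply(config$designs, function(d) {
      draws <- sample_posterior_predictive(
        mcmc[[d]], n_per_chain = config$forecast_per_chain,
        seed = config$seed + 11L)
      forecast_uq(draws, params, chains = mcmc[[d]],
                  init_state = truth_state, seed = config$seed + 13L)
    })
    names(out) <- config$designs
    out
  })
  if (!is.null(forecasts)) {
    truth_sim <- .obs_simulate(params, .default_obs_opts(), truth_state)
    report$forecast_summaries <- lapply(forecasts, summarize_forecast,
                                        truth_sim = truth_sim)
  }

  report$subset <- subset
  report$elapsed <- as.numeric(Sys.time() - t_all, units = "secs")
  report <- structure(report, class = "cv_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (d in names(datasets)) write_dataset(datasets[[d]], out_dir)
    jsonlite::write_json(
      list(counts = as.list(report$counts), subset = subset,
           classifications = report$classifications,
           elapsed = report$elapsed),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    emit_provenance(file.path(out_dir, "report.json"),
                    config = unclass(config),
                    inputs = c(params = .params_hash(params)))
  }
  report$results <- list(selection = selection, profiles = profiles,
                         mcmc = mcmc, forecasts = forecasts,
                         datasets = datasets)
  report
}

#' @export
print.cv_report <- function(x, ...) {
  cat("<cv_report>", x$config$scale, "preset -",
      sprintf("%.1f s total\n", x$elapsed %||% NA_real_))
  for (nm in names(x$stages))
    cat(sprintf("  %-20s %s\n", nm,
                if (x$stages[[nm]]$ok) sprintf("ok (%.1f s)",
                                               x$stages[[nm]]$seconds)
                else paste("FAILED:", x$stages[[nm]]$error)))
  if (!is.null(x$counts))
    cat("  parameter reduction:", paste(x$counts, collapse = " -> "), "\n")
  invisible(x)
}

#' Write a provenance sidecar for an artifact
#'
#' Records the configuration, input hashes, package version and the
#' artifact's own checksum so that a pipeline run can be re-validated
#' and reconstructed stage by stage.
#'
#' @param path artifact file path (must exist)
#' @param config list of settings that produced the artifact
#' @param inputs named character vector of upstream artifact hashes
#' @return sidecar path, invisibly
#' @export
emit_provenance <- function(path, config = list(), inputs = character(0)) {
  stopifnot(file.exists(path))
  side <- paste0(path, ".prov.json")
  jsonlite::write_json(
    list(artifact = basename(path),
         md5 = unname(tools::md5sum(path)),
         inputs = as.list(inputs),
         config = config,
         package_version = as.character(utils::packageVersion("cvident")),
         created = format(Sys.time(), tz = "UTC")),
    side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Validate a provenance sidecar
#'
#' @param path artifact path with an adjacent `.prov.json` sidecar
#' @return `TRUE` if the artifact checksum matches; `FALSE` otherwise
#' @export
check_provenance <- function(path) {
  side <- paste0(path, ".prov.json")
  if (!file.exists(side)) return(FALSE)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  identical(unname(tools::md5sum(path)), meta$md5)
}
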