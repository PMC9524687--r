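#' @useDynLib cvident, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim qchisq rnorm runif sd median quantile density cor var setNames
#' @importFrom utils write.csv read.csv modifyList packageVersion
NULL

KPA_PER_MMHG <- 1 / 7.50062
MMHG_PER_KPA <- 7.50062

.sarc_fields <- c("Ls_ref", "Ls_iso", "v0", "Lsc0", "gamma_rest", "tau_rise",
                  "tau_decay", "tau_sys", "sigma_act", "sigma_pas",
                  "Ls_pas_ref", "beta_pas", "k1")
.walls <- c("LA", "LV", "RA", "RV", "S")
.compartments <- c("LA", "LV", "RA", "RV", "SA", "SV", "PA", "PV")

#' Canonical names of the 49 model parameters
#'
#' The parameter vector concatenates, in fixed order: the 13 atrial
#' sarcomere parameters, the 13 ventricular sarcomere parameters, the
#' atrial activation delay, five wall volumes, five reference mid-wall
#' areas, eight resistances, and four compliances.
#'
#' @return character vector of length 49
#' @export
cv_param_names <- function() {
  c(paste0(.sarc_fields, "_A"),
    paste0(.sarc_fields, "_V"),
    "tau_offset_A",
    paste0("Vw_", .walls),
    paste0("Am_ref_", .walls),
    "Ra_val", "Rm_val", "Rp_val", "Rt_val", "R_vc", "R_pv", "R_sys", "R_pulm",
    "C_sa", "C_sv", "C_pa", "C_pv")
}

#' Parameters held fixed a priori in all sensitivity analyses
#'
#' Microscale sarcomere reference quantities (reference/isometric/contractile
#' element lengths, resting contractility, passive reference length) and the
#' atrial activation delay are fixed for physiological reasons, leaving 38
#' varied parameters.
#'
#' @return character vector of length 11
#' @export
cv_fixed_names <- function() {
  c(paste0(rep(c("Ls_ref", "Ls_iso", "Lsc0", "gamma_rest", "Ls_pas_ref"),
               each = 2), c("_A", "_V")),
    "tau_offset_A")
}

#' Names of the 38 parameters varied in sensitivity analyses
#' @return character vector of length 38
#' @export
cv_varied_names <- function() {
  setdiff(cv_param_names(), cv_fixed_names())
}

#' Units of the canonical parameters
#' @return named character vector
#' @export
cv_param_units <- function() {
  u <- c(Ls_ref = "um", Ls_iso = "um", v0 = "um/s", Lsc0 = "um",
         gamma_rest = "-", tau_rise = "s", tau_decay = "s", tau_sys = "s",
         sigma_act = "kPa", sigma_pas = "kPa", Ls_pas_ref = "um",
         beta_pas = "-", k1 = "-")
  out <- c(setNames(u, paste0(names(u), "_A")),
           setNames(u, paste0(names(u), "_V")),
           tau_offset_A = "s",
           setNames(rep("mm3", 5), paste0("Vw_", .walls)),
           setNames(rep("mm2", 5), paste0("Am_ref_", .walls)),
           setNames(rep("kPa.s/ul", 8),
                    c("Ra_val", "Rm_val", "Rp_val", "Rt_val", "R_vc", "R_pv",
                      "R_sys", "R_pulm")),
           setNames(rep("ul/kPa", 4), c("C_sa", "C_sv", "C_pa", "C_pv")))
  out[cv_param_names()]
}

.default_config <- function() {
  list(period = 0.11,
       V_un = c(SA = 0, SV = 0, PA = 0, PV = 0),
       init_volumes = c(LA = 22, LV = 50, RA = 22, RV = 50,
                        SA = 55, SV = 120, PA = 14, PV = 30))
}

#' Construct a model parameter object
#'
#' @param theta named numeric vector with the 49 canonical parameters
#'   (see [cv_param_names()]); order is normalized internally.
#' @param config list with elements `period` (cardiac period, s), `V_un`
#'   (unstressed volumes of the four vascular compartments, ul) and
#'   `init_volumes` (initial compartment volumes, ul). Missing elements
#'   fall back to the shipped defaults.
#' @return object of class `cv_params`
#' @export
cv_params <- function(theta, config = list()) {
  nm <- cv_param_names()
  if (is.null(names(theta)) || !setequal(names(theta), nm) ||
      length(theta) != 49L) {
    missing <- setdiff(nm, names(theta))
    extra <- setdiff(names(theta), nm)
    stop("theta must contain exactly the 49 canonical parameters",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; unknown: ",
                                   paste(extra, collapse = ", ")))
  }
  cfg <- utils::modifyList(.default_config(), config)
  cfg$V_un <- unlist(cfg$V_un)[c("SA", "SV", "PA", "PV")]
  cfg$init_volumes <- unlist(cfg$init_volumes)[.compartments]
  obj <- structure(list(theta = as.numeric(theta[nm]), config = cfg),
                   class = "cv_params")
  names(obj$theta) <- nm
  obj
}

#' @export
print.cv_params <- function(x, ...) {
  cat("<cv_params>: 49-parameter multiscale cardiovascular model\n")
  cat(sprintf("  period: %g s, total initial stressed volume: %g ul\n",
              x$config$period, sum(x$config$init_volumes)))
  print(round(x$theta, 6))
  invisible(x)
}

#' Validate a parameter object or named vector
#'
#' Performs the full schema check (49 canonical names, positivity and
#' sign constraints, finite values) and returns an exhaustive list of
#' problems rather than failing at the first.
#'
#' @param params a `cv_params` object, or a named numeric vector of 49 values
#' @return character vector of problems; `character(0)` when valid
#' @export
validate_params <- function(params) {
  problems <- character(0)
  if (!inherits(params, "cv_params")) {
    params <- tryCatch(cv_params(params), error = function(e) e)
    if (inherits(params, "error")) return(conditionMessage(params))
  }
  th <- params$theta
  if (any(!is.finite(th)))
    problems <- c(problems, paste0("non-finite value for: ",
                                   paste(names(th)[!is.finite(th)],
                                         collapse = ", ")))
  nonneg_ok <- grepl("^(gamma_rest|tau_offset)", names(th))
  bad <- is.finite(th) & ((th <= 0 & !nonneg_ok) | (th < 0 & nonneg_ok))
  if (any(bad))
    problems <- c(problems, paste0("positivity violated for: ",
                                   paste(names(th)[bad], collapse = ", ")))
  if (!is.finite(params$config$period) || params$config$period <= 0)
    problems <- c(problems, "config$period must be a positive number")
  if (any(params$config$V_un < 0 | !is.finite(params$config$V_un)))
    problems <- c(problems, "config$V_un must be finite and >= 0")
  if (any(params$config$init_volumes <= 0 |
          !is.finite(params$config$init_volumes)))
    problems <- c(problems, "config$init_volumes must be finite and > 0")
  problems
}

.assert_params <- function(params) {
  if (!inherits(params, "cv_params")) params <- cv_params(params)
  pr <- validate_params(params)
  if (length(pr)) stop("invalid model parameters:\n  ",
                       paste(pr, collapse = "\n  "))
  params
}

# pack parameters + config into the flat 54-vector used by compiled code
.pack_params <- function(params) {
  params <- .assert_params(params)
  c(params$theta, params$config$period, params$config$V_un)
}

#' Load the shipped nominal mouse parameter file
#'
#' Nominal ("true") parameter values for a normotensive mouse; all
#' synthetic-data generation and identifiability analyses treat these as
#' the data-generating truth.
#'
#' @return a `cv_params` object
#' @export
nominal_params <- function() {
  load_params(system.file("extdata", "nominal_mouse.yaml", package = "cvident",
                          mustWork = TRUE))
}

#' Read model parameters from a YAML file
#'
#' The file must contain a `parameters` block with exactly the 49
#' canonical names and may contain a `config` block (period, unstressed
#' volumes, initial volumes). Unknown or missing parameter keys are
#' rejected.
#'
#' @param file path to a YAML parameter file
#' @return a `cv_params` object
#' @export
load_params <- function(file) {
  doc <- yaml::read_yaml(file)
  if (is.null(doc$parameters)) stop("parameter file lacks a 'parameters' block")
  theta <- unlist(doc$parameters)
  extra_blocks <- setdiff(names(doc), c("parameters", "config"))
  if (length(extra_blocks))
    stop("unknown top-level blocks in parameter file: ",
         paste(extra_blocks, collapse = ", "))
  .assert_params(cv_params(theta, config = doc$config %||% list()))
}

#' Write model parameters to a YAML file
#'
#' The on-disk representation round-trips losslessly through
#' [load_params()].
#'
#' @param params a `cv_params` object
#' @param file output path
#' @return `file`, invisibly
#' @export
save_params <- function(params, file) {
  params <- .assert_params(params)
  doc <- list(parameters = as.list(params$theta),
              config = list(period = params$config$period,
                            V_un = as.list(params$config$V_un),
                            init_volumes = as.list(params$config$init_volumes)))
  yaml::write_yaml(doc, file, precision = 17L)
  invisible(file)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Define the sampled parameter space for screening and inference
#'
#' Maps each varied parameter to the unit interval via its bounds;
#' defaults to +/-50% around the nominal value.
#'
#' @param params nominal `cv_params`
#' @param varied character vector of parameter names to vary
#'   (default: the 38 used in sensitivity analyses)
#' @param lower,upper optional named vectors overriding individual bounds
#' @param span half-width of the default relative bounds (0.5 gives
#'   `[0.5, 1.5] * nominal`)
#' @return object of class `cv_space` with fields `names`, `nominal`,
#'   `lower`, `upper`
#' @export
parameter_space <- function(params, varied = cv_varied_names(),
                            lower = NULL, upper = NULL, span = 0.5) {
  params <- .assert_params(params)
  stopifnot(all(varied %in% cv_param_names()))
  nom <- params$theta[varied]
  lo <- nom * (1 - span)
  hi <- nom * (1 + span)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  if (any(lo >= hi)) stop("lower bounds must be below upper bounds")
  structure(list(names = varied, nominal = nom, lower = lo, upper = hi,
                 params = params),
            class = "cv_space")
}

#' Map unit-hypercube coordinates to a full parameter object
#'
#' @param u numeric vector in `[0,1]^d` matching `space$names`
#' @param space a `cv_space`
#' @return a `cv_params` with the varied entries replaced
#' @export
space_to_params <- function(u, space) {
  stopifnot(inherits(space, "cv_space"), length(u) == length(space$names))
  th <- space$params$theta
  th[space$names] <- space$lower + u * (space$upper - space$lower)
  cv_params(th, space$params$config)
}

# replace a subset of parameters by name in a cv_params
.with_theta <- function(params, values) {
  th <- params$theta
  th[names(values)] <- values
  cv_params(th, params$config)
}

# deterministic md5 hash of the parameter values, for provenance
.params_hash <- function(params) {
  v <- c(params$theta, period = params$config$period, params$config$V_un,
         params$config$init_volumes)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(names(v), sprintf("%.17g", v)), f)
  unname(tools::md5sum(f))
}

#' Reference 13-parameter inference subset
#'
#' The canonical subset of practically identifiable parameters used by
#' the profile-likelihood and Bayesian stages: the three ventricular
#' wall volumes, three reference areas (left atrium and both
#' ventricular free walls), the four ventricular activation/active
#' stress parameters, and the three dominant hemodynamic parameters.
#'
#' @return character vector of 13 parameter names
#' @export
cv_reference_subset <- function() {
  c("Vw_LV", "Vw_RV", "Vw_S", "Am_ref_LA", "Am_ref_LV", "Am_ref_RV",
    "tau_rise_V", "tau_decay_V", "tau_sys_V", "sigma_act_V",
    "R_sys", "R_pulm", "C_pa")
}
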