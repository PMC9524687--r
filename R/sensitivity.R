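#' Morris elementary-effect step size
#'
#' For an `l`-level grid on the unit interval the screening step is
#' `delta = l / (2 (l - 1))`, which approaches 1/2 for large `l`.
#'
#' @param l number of grid levels (even values give a symmetric
#'   sampling distribution; odd values trigger a warning)
#' @return the step `delta`
#' @export
morris_step <- function(l) {
  stopifnot(l >= 2)
  if (l %% 2 != 0)
    warning("an even number of Morris levels is recommended for symmetry")
  l / (2 * (l - 1))
}

#' Elementary-effects screening of a vector-valued function
#'
#' Generic Morris screening engine on the unit hypercube using
#' randomized trajectories on an `l`-level grid. Each trajectory
#' perturbs every coordinate exactly once by `+/- delta`; elementary
#' effects are computed from consecutive point pairs. Function failures
#' (`NA` rows) invalidate only the elementary effects whose endpoints
#' are affected.
#'
#' @param fun function taking a numeric vector in `[0,1]^d` and
#'   returning a numeric vector of `F` outputs, or `NULL`/`NA`s on
#'   failure
#' @param d dimension of the input space
#' @param K number of random trajectories
#' @param l number of grid levels
#' @param seed RNG seed
#' @param max_fail_frac abort when more than this fraction of
#'   elementary effects is lost to failures
#' @return object of class `cv_morris` with matrices `mu`, `mu_star`,
#'   `s2` and `M` (`d x F`), the per-parameter effect counts `K_eff`,
#'   and bookkeeping fields
#' @export
morris_elementary_effects <- function(fun, d, K = 100, l = 60, seed = 1L,
                                      max_fail_frac = 0.2) {
  delta <- morris_step(l)
  set.seed(seed)
  levels_lo <- (seq_len(l / 2) - 1) / (l - 1)  # levels with room for +delta
  ee <- NULL  # list of d-column matrices, one row per trajectory per output
  n_out <- NULL
  ee_list <- vector("list", K)
  n_lost <- 0L
  n_total <- 0L
  for (k in seq_len(K)) {
    x0 <- sample(levels_lo, d, replace = TRUE)
    dir <- sample(c(-1, 1), d, replace = TRUE)
    x0 <- ifelse(dir < 0, x0 + delta, x0)
    ord <- sample.int(d)
    pts <- matrix(NA_real_, d + 1, d)
    pts[1, ] <- x0
    for (s in seq_len(d)) {
      pts[s + 1, ] <- pts[s, ]
      pts[s + 1, ord[s]] <- pts[s, ord[s]] + dir[ord[s]] * delta
    }
    vals <- lapply(seq_len(d + 1), function(i) {
      v <- tryCatch(fun(pts[i, ]), error = function(e) NULL)
      if (is.null(v) || any(!is.finite(v))) NULL else v
    })
    if (is.null(n_out)) {
      ok1 <- which(!vapply(vals, is.null, TRUE))[1]
      if (is.na(ok1)) { n_lost <- n_lost + d; n_total <- n_total + d; next }
      n_out <- length(vals[[ok1]])
    }
    eek <- matrix(NA_real_, d, n_out)
    for (s in seq_len(d)) {
      n_total <- n_total + 1L
      a <- vals[[s]]; b <- vals[[s + 1]]
      if (is.null(a) || is.null(b)) { n_lost <- n_lost + 1L; next }
      eek[ord[s], ] <- dir[ord[s]] * (b - a) / delta
    }
    ee_list[[k]] <- eek
  }
  if (n_total == 0 || n_lost / n_total > max_fail_frac)
    stop(sprintf(paste0("Morris screening aborted: %d of %d elementary ",
                        "effects lost to model failures"), n_lost, n_total))
  arr <- array(NA_real_, c(K, d, n_out))
  for (k in seq_len(K)) if (!is.null(ee_list[[k]])) arr[k, , ] <- ee_list[[k]]
  agg <- function(f) apply(arr, c(2, 3), f, na.rm = TRUE)
  mu <- agg(mean)
  mu_star <- apply(abs(arr), c(2, 3), mean, na.rm = TRUE)
  s2 <- apply(arr, c(2, 3), stats::var, na.rm = TRUE)
  s2[!is.finite(s2)] <- 0
  K_eff <- apply(!is.na(arr[, , 1, drop = FALSE]), 2, sum)
  M <- sqrt(mu_star^2 + s2)
  structure(list(mu = mu, mu_star = mu_star, s2 = s2, M = M,
                 K = K, K_eff = K_eff, l = l, delta = delta, seed = seed,
                 n_lost = n_lost, n_total = n_total),
            class = "cv_morris")
}

#' @export
print.cv_morris <- function(x, ...) {
  cat(sprintf("<cv_morris> %d parameters x %d outputs, K = %d (l = %d, delta = %.3f)\n",
              nrow(x$M), ncol(x$M), x$K, x$l, x$delta))
  cat(sprintf("  elementary effects lost to failures: %d / %d\n",
              x$n_lost, x$n_total))
  invisible(x)
}

#' Morris screening of the cardiovascular model
#'
#' Screens the varied parameters over their bounds (mapped to the unit
#' hypercube) against the squared 2-norms of the four ventricular
#' outputs (RV/LV pressure and volume, in observation units).
#'
#' @param space a `cv_space` from [parameter_space()]
#' @param K number of trajectories
#' @param l number of grid levels
#' @param seed RNG seed
#' @param n_cycles,rtol,atol simulator settings for the screening runs
#' @param init_state warm-start state; computed from the space's
#'   nominal parameters when missing
#' @param outputs model signals screened (reduced to squared 2-norms)
#' @return a `cv_morris` with parameter names attached
#' @export
morris_screen <- function(space, K = 100, l = 60, seed = 1L,
                          n_cycles = 12, rtol = 1e-4, atol = 1e-4,
                          init_state = NULL,
                          outputs = c("p_RV", "p_LV", "V_RV", "V_LV")) {
  stopifnot(inherits(space, "cv_space"))
  if (is.null(init_state))
    init_state <- steady_state(space$params, n_cycles = 30,
                               rtol = 1e-6, atol = 1e-6)
  fun <- function(u) {
    p <- space_to_params(u, space)
    sim <- simulate_model(p, n_cycles = n_cycles, rtol = rtol, atol = atol,
                          init_state = init_state)
    vapply(outputs, function(s)
      sum(.obs_units(sim$signals[[s]], s)^2), numeric(1))
  }
  res <- morris_elementary_effects(fun, d = length(space$names), K = K,
                                   l = l, seed = seed)
  dimnames(res$mu) <- dimnames(res$mu_star) <- dimnames(res$s2) <-
    dimnames(res$M) <- list(space$names, outputs)
  res$space <- space
  res
}

#' Fix non-influential parameters after Morris screening
#'
#' A parameter is fixed when its combined index `M = sqrt(mu_star^2 +
#' s2)` falls strictly below the across-parameter mean index for every
#' output; all other parameters are retained.
#'
#' @param morris a `cv_morris` (with named rows)
#' @return list with `retained`, `fixed` (character vectors) and the
#'   per-output mean indices `M_bar`
#' @export
fix_noninfluential <- function(morris) {
  stopifnot(inherits(morris, "cv_morris"))
  M <- morris$M
  if (is.null(rownames(M))) rownames(M) <- paste0("theta", seq_len(nrow(M)))
  M_bar <- colMeans(M)
  below_all <- apply(sweep(M, 2, M_bar, "<"), 1, all)
  list(retained = rownames(M)[!below_all],
       fixed = rownames(M)[below_all],
       M_bar = M_bar)
}

#' Log-scaled local sensitivity of a design's observation vector
#'
#' Centered finite differences of the full observation vector of a
#' design with respect to each subset parameter, scaled by the nominal
#' parameter value (derivative with respect to log theta).
#'
#' @param params nominal `cv_params`
#' @param subset character vector of parameter names to differentiate
#' @param design a `cv_design` (or design id string)
#' @param step_frac relative step for the centered difference
#' @param obs_opts simulator settings; the default integrates 30
#'   warm-started cycles at tolerance 1e-8 so that finite-difference
#'   derivatives are not contaminated by solver error
#' @param init_state warm-start state (computed when missing)
#' @return object of class `cv_localsens`: `S` (observations x
#'   parameters, log-scaled), `S_bar` (squared 2-norm per channel per
#'   parameter), `steps`
#' @export
local_sensitivity <- function(params, subset, design, step_frac = 0.01,
                              obs_opts = NULL, init_state = NULL) {
  params <- .assert_params(params)
  if (is.character(design)) design <- experimental_design(design)
  tight <- list(n_cycles = 30, rtol = 1e-8, atol = 1e-8, n_out = 100)
  opts <- utils::modifyList(tight, obs_opts %||% list())
  if (is.null(init_state))
    init_state <- steady_state(params, n_cycles = 30, rtol = 1e-6,
                               atol = 1e-6)
  obs_at <- function(p) {
    sim <- .obs_simulate(p, opts, init_state)
    extract_observations(sim, design)
  }
  run_pair <- function(nm, frac) {
    th <- params$theta[nm]
    dd <- frac * abs(th)
    up <- obs_at(.with_theta(params, setNames(th + dd, nm)))
    dn <- obs_at(.with_theta(params, setNames(th - dd, nm)))
    list(up = up, dn = dn, dd = dd)
  }
  chan_names <- names(design$channels)
  S_cols <- list()
  steps <- numeric(0)
  for (nm in subset) {
    pr <- tryCatch(run_pair(nm, step_frac), error = function(e) NULL)
    if (is.null(pr))  # one retry with a halved step, then give up
      pr <- tryCatch(run_pair(nm, step_frac / 2), error = function(e)
        stop("local sensitivity failed for parameter ", nm))
    dy <- unlist(pr$up) - unlist(pr$dn)
    S_cols[[nm]] <- dy / (2 * pr$dd) * params$theta[nm]
    steps[nm] <- pr$dd
  }
  S <- do.call(cbind, S_cols)
  ch_id <- rep(chan_names, times = vapply(design$channels, function(ch)
    if (ch$kind == "series") as.integer(opts$n_out) else 1L, integer(1)))
  S_bar <- t(vapply(split(as.data.frame(S), ch_id)[unique(ch_id)],
                    function(df) colSums(as.matrix(df)^2), numeric(ncol(S))))
  structure(list(S = S, S_bar = S_bar, steps = steps, design = design,
                 subset = subset, step_frac = step_frac),
            class = "cv_localsens")
}

#' Fisher information matrix from a sensitivity matrix
#'
#' @param S sensitivity matrix (observations x parameters)
#' @return `t(S) %*% S`, symmetric positive semi-definite
#' @export
fisher_information <- function(S) {
  stopifnot(all(is.finite(S)))
  crossprod(S)
}

# condition number of F via its singular values
.cond_F <- function(F) {
  sv <- svd(F, nu = 0, nv = 0)$d
  if (min(sv) <= 0) return(Inf)
  max(sv) / min(sv)
}

#' SVD-based subset reduction of ill-conditioned Fisher matrices
#'
#' While any design's Fisher information matrix has condition number
#' above `cond_max`, the parameter with the largest-magnitude component
#' in the right singular vector of the smallest singular value (of the
#' worst-conditioned design) is removed, and all designs are
#' re-assembled without it. Near-equal components (within 1e-12) are
#' broken toward the later parameter in canonical order.
#'
#' @param S_list named list (one per design) of sensitivity matrices
#'   with identical column names
#' @param cond_max condition-number bound
#' @return object of class `cv_subset`: `retained`, `removed` (in
#'   removal order), `trail` (data frame audit of each removal),
#'   `cond_before`, `cond_after` (per design)
#' @export
svd_subset_reduce <- function(S_list, cond_max = 1e8) {
  stopifnot(length(S_list) >= 1)
  params <- colnames(S_list[[1]])
  for (S in S_list) stopifnot(identical(colnames(S), params))
  keep <- params
  removed <- character(0)
  trail <- list()
  cond_before <- vapply(S_list, function(S) .cond_F(fisher_information(S)),
                        numeric(1))
  repeat {
    conds <- vapply(S_list, function(S)
      .cond_F(fisher_information(S[, keep, drop = FALSE])), numeric(1))
    if (all(conds <= cond_max)) break
    if (length(keep) <= 2)
      stop("SVD reduction would leave fewer than 2 parameters")
    worst <- which.max(conds)
    F <- fisher_information(S_list[[worst]][, keep, drop = FALSE])
    v <- abs(svd(F)$v[, length(keep)])
    cand <- which(v >= max(v) - 1e-12)
    drop_i <- max(cand)  # ties: later canonical order
    trail[[length(trail) + 1]] <- data.frame(
      removed = keep[drop_i], design = names(S_list)[worst],
      cond = conds[worst], n_before = length(keep))
    removed <- c(removed, keep[drop_i])
    keep <- keep[-drop_i]
  }
  cond_after <- vapply(S_list, function(S)
    .cond_F(fisher_information(S[, keep, drop = FALSE])), numeric(1))
  structure(list(retained = keep, removed = removed,
                 trail = if (length(trail)) do.call(rbind, trail) else NULL,
                 cond_before = cond_before, cond_after = cond_after,
                 cond_max = cond_max),
            class = "cv_subset")
}

#' @export
print.cv_subset <- function(x, ...) {
  cat(sprintf("<cv_subset> %d parameters retained (removed %d at cond_max %.1e)\n",
              length(x$retained), length(x$removed), x$cond_max))
  cat("  retained:", paste(x$retained, collapse = ", "), "\n")
  if (length(x$removed))
    cat("  removed:", paste(x$removed, collapse = ", "), "\n")
  invisible(x)
}

#' Full sensitivity-based subset-selection workflow
#'
#' Runs the staged parameter reduction: the 49 model parameters are
#' restricted a priori to the 38 varied ones, Morris screening fixes
#' the globally non-influential parameters, and SVD reduction of the
#' per-design Fisher matrices removes locally interdependent parameters
#' until every design's Fisher information is acceptably conditioned.
#'
#' @param params nominal `cv_params`
#' @param K,l,seed Morris settings
#' @param morris_span half-width of the relative screening bounds
#' @param designs design ids used for the local stage
#' @param cond_max Fisher condition-number bound
#' @param step_frac local-sensitivity step
#' @param obs_opts observation-simulator settings for the local stage
#' @return object of class `cv_selection` with per-stage sets and audit
#'   information
#' @export
subset_selection <- function(params, K = 100, l = 60, seed = 1L,
                             morris_span = 0.25,
                             designs = c("f1", "f2", "f3", "f4"),
                             cond_max = 1e8, step_frac = 0.01,
                             obs_opts = NULL) {
  params <- .assert_params(params)
  init_state <- steady_state(params, n_cycles = 30, rtol = 1e-6, atol = 1e-6)
  space <- parameter_space(params, span = morris_span)
  morris <- morris_screen(space, K = K, l = l, seed = seed,
                          init_state = init_state)
  fixing <- fix_noninfluential(morris)
  sens <- lapply(designs, function(d)
    local_sensitivity(params, fixing$retained, d, step_frac = step_frac,
                      obs_opts = obs_opts, init_state = init_state))
  names(sens) <- designs
  svd_sel <- svd_subset_reduce(lapply(sens, `[[`, "S"), cond_max = cond_max)
  structure(list(varied = space$names, morris = morris,
                 morris_retained = fixing$retained,
                 morris_fixed = fixing$fixed,
                 local = sens, svd = svd_sel,
                 final = svd_sel$retained,
                 counts = c(total = 49L, varied = length(space$names),
                            after_morris = length(fixing$retained),
                            final = length(svd_sel$retained))),
            class = "cv_selection")
}

#' @export
print.cv_selection <- function(x, ...) {
  cat("<cv_selection> staged parameter reduction:",
      paste(x$counts, collapse = " -> "), "\n")
  cat("  final subset:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}
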