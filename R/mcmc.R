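#' Bounded uniform prior for a parameter subset
#'
#' Minimally informative box prior, by default +/-50% around the
#' reference values; the truth is strictly inside the support.
#'
#' @param params_ref `cv_params` with reference values
#' @param subset parameter names
#' @param span relative half-width
#' @return object of class `cv_prior` with `lower`, `upper`
#' @export
uniform_prior <- function(params_ref, subset, span = 0.5) {
  th <- .assert_params(params_ref)$theta[subset]
  structure(list(lower = th * (1 - span), upper = th * (1 + span),
                 subset = subset, span = span),
            class = "cv_prior")
}

# log-density of the box prior (0 inside, -Inf outside)
.log_prior <- function(prior, theta) {
  if (all(theta >= prior$lower) && all(theta <= prior$upper)) 0 else -Inf
}

#' Guard an objective against simulation crashes
#'
#' Wraps a residual-sum-of-squares (or any) objective so that model
#' failures map to a large penalty value instead of an error, keeping
#' optimizers and MCMC chains alive; each failure is recorded on the
#' returned function's environment.
#'
#' @param fun objective function of a parameter vector
#' @param penalty value returned on failure (default `1e10`)
#' @return guarded function with attributes `penalty` and a `failures`
#'   environment collecting the failing parameter vectors
#' @export
crash_guard <- function(fun, penalty = CRASH_SSE) {
  log_env <- new.env(parent = emptyenv())
  log_env$failures <- list()
  g <- function(theta) {
    v <- tryCatch(fun(theta), error = function(e) NULL)
    if (is.null(v) || !is.finite(v)) {
      log_env$failures[[length(log_env$failures) + 1]] <- theta
      return(penalty)
    }
    v
  }
  attr(g, "penalty") <- penalty
  attr(g, "log") <- log_env
  g
}

# weighted residual vector (units of noise sd) of a dataset at params
.residual_vector <- function(dataset, params, init_state) {
  opts <- dataset$meta$obs_opts %||% .default_obs_opts()
  sim <- .obs_simulate(params, opts, init_state)
  obs <- extract_observations(sim, dataset$design)
  unlist(lapply(names(dataset$y), function(nm)
    (dataset$y[[nm]] - obs[[nm]]) / sqrt(dataset$sigma2[[nm]])))
}

#' Multi-start optimization initialization for MCMC
#'
#' Draws starting points from the prior, minimizes the (crash-guarded)
#' weighted residual sum of squares from each, and returns the optima
#' together with Gauss-Newton proposal covariances (inverse of `J'J`
#' from a finite-difference residual Jacobian, regularized to be
#' positive definite).
#'
#' @param dataset a `cv_dataset`
#' @param subset inferred parameter names
#' @param params_ref `cv_params` carrying the fixed parameters
#' @param prior a `cv_prior` (defaults to +/-50% around the reference)
#' @param n_starts number of random starts
#' @param seed RNG seed
#' @param maxit Nelder-Mead budget per start
#' @param n_restarts simplex restarts per start (a collapsed simplex is
#'   rebuilt at the incumbent until no further improvement)
#' @param n_hops basin-hopping jumps applied to the best start:
#'   perturbations along the Gauss-Newton covariance (the likelihood
#'   valley's long axes) followed by re-polishing
#' @param init_state warm-start state for the simulator
#' @return list of `list(theta, value, cov)` sorted by objective value
#' @export
initialize_starts <- function(dataset, subset, params_ref, prior = NULL,
                              n_starts = 12, seed = 1L, maxit = 300,
                              n_restarts = 3, n_hops = 0,
                              init_state = NULL) {
  params_ref <- .assert_params(params_ref)
  if (is.null(prior)) prior <- uniform_prior(params_ref, subset)
  if (is.null(init_state))
    init_state <- steady_state(params_ref, n_cycles = 30, rtol = 1e-6,
                               atol = 1e-6)
  th_ref <- params_ref$theta[subset]
  sse_fun <- crash_guard(function(th) {
    # optimization is confined to the prior support
    if (any(th < prior$lower) || any(th > prior$upper)) stop("outside prior")
    r <- .residual_vector(dataset,
                          .with_theta(params_ref, setNames(th, subset)),
                          init_state)
    sum(r^2)
  })
  set.seed(seed)
  obj <- function(x) sse_fun(x * th_ref)
  nm <- function(x0, budget) stats::optim(x0, obj, method = "Nelder-Mead",
                                          control = list(maxit = budget,
                                                         reltol = 1e-9))
  # iterated Nelder-Mead: restarting rebuilds the collapsed simplex
  polish <- function(x0) {
    cur <- x0; best <- Inf
    for (k in seq_len(n_restarts)) {
      o <- nm(cur, maxit)
      cur <- o$par
      if (o$value > best - 0.5) { best <- min(best, o$value); break }
      best <- o$value
    }
    list(par = cur, value = best)
  }
  starts <- list()
  attempt <- 0L
  while (length(starts) < n_starts && attempt < 4L * n_starts) {
    attempt <- attempt + 1L
    th0 <- stats::runif(length(subset), prior$lower, prior$upper)
    o <- polish(th0 / th_ref)
    if (!is.finite(o$value) || o$value >= attr(sse_fun, "penalty")) next
    starts[[length(starts) + 1]] <- list(par = o$par, value = o$value)
  }
  if (length(starts) < n_starts)
    warning(sprintf("only %d of %d optimization starts succeeded",
                    length(starts), n_starts))
  starts <- starts[order(vapply(starts, `[[`, numeric(1), "value"))]
  # basin hopping on the best start: jump along the Gauss-Newton ridge
  # directions and re-polish, escaping the local minima that line the
  # likelihood valley
  if (length(starts) && n_hops > 0) {
    cur <- starts[[1]]$par
    f <- starts[[1]]$value
    gncov <- function(x) .gauss_newton_cov(dataset, params_ref, subset,
                                           x * th_ref, init_state) /
      tcrossprod(th_ref)
    L <- tryCatch(chol(gncov(cur) + diag(1e-12, length(cur))),
                  error = function(e) diag(0.01, length(cur)))
    for (hop in seq_len(n_hops)) {
      xp <- cur + as.numeric(t(L) %*% stats::rnorm(length(cur))) * 3
      o <- nm(xp, max(200, maxit %/% 2))
      if (is.finite(o$value) && o$value < f - 0.5) {
        cur <- o$par; f <- o$value
        L <- tryCatch(chol(gncov(cur) + diag(1e-12, length(cur))),
                      error = function(e) L)
      }
    }
    starts[[1]] <- list(par = cur, value = f)
  }
  lapply(starts, function(st) {
    theta_sse <- st$par * th_ref
    list(theta = theta_sse, value = st$value,
         cov = .gauss_newton_cov(dataset, params_ref, subset, theta_sse,
                                 init_state))
  })
}

#' Gauss-Newton proposal covariance of a least-squares problem
#'
#' Approximates the inverse Hessian of `0.5 * sum(r(theta)^2)` by
#' `(J'J)^-1` with a one-sided finite-difference residual Jacobian `J`,
#' eigenvalue-clipped to be positive definite. Exact for linear
#' residual models.
#'
#' @param resid_fun function returning the residual vector at `theta`
#' @param theta evaluation point
#' @param rel_step relative finite-difference step
#' @return covariance matrix (or `NULL` if any evaluation fails)
#' @export
gauss_newton_covariance <- function(resid_fun, theta, rel_step = 1e-3) {
  r0 <- tryCatch(resid_fun(theta), error = function(e) NULL)
  if (is.null(r0)) return(NULL)
  d <- length(theta)
  J <- matrix(NA_real_, length(r0), d)
  for (j in seq_len(d)) {
    dd <- rel_step * max(abs(theta[j]), 1e-12)
    tp <- theta; tp[j] <- tp[j] + dd
    rp <- tryCatch(resid_fun(tp), error = function(e) NULL)
    if (is.null(rp)) return(NULL)
    J[, j] <- (rp - r0) / dd
  }
  H <- crossprod(J)
  ev <- eigen(H, symmetric = TRUE)
  lam <- pmax(ev$values, max(ev$values) * 1e-10, 1e-12)
  cov <- ev$vectors %*% diag(1 / lam, d) %*% t(ev$vectors)
  dimnames(cov) <- list(names(theta), names(theta))
  cov
}

# dataset-bound wrapper with a diagonal fallback
.gauss_newton_cov <- function(dataset, params_ref, subset, theta,
                              init_state, rel_step = 1e-3) {
  cov <- gauss_newton_covariance(function(th)
    .residual_vector(dataset,
                     .with_theta(params_ref, setNames(th, subset)),
                     init_state),
    theta, rel_step = rel_step)
  if (is.null(cov))
    cov <- diag(pmax(1e-4 * abs(theta), 1e-8)^2, length(theta))
  cov
}

#' Delayed-rejection adaptive-Metropolis sampler
#'
#' Generic DRAM engine for an arbitrary log-posterior: Gaussian
#' random-walk Metropolis with one delayed-rejection stage (second
#' proposal narrowed by `1/dr_scale`) and covariance adaptation from
#' the accumulated chain every `adapt_interval` iterations (scale
#' `2.38^2/d`, ridge `eps`).
#'
#' @param log_post function returning the (unnormalized) log posterior
#' @param start numeric starting vector
#' @param cov0 initial proposal covariance
#' @param n_iter total iterations
#' @param seed RNG seed (chains with distinct seeds are independent)
#' @param adapt_interval iterations between covariance updates
#' @param dr_scale narrowing factor of the delayed-rejection stage
#' @param eps ridge added during adaptation
#' @return object of class `cv_chain`: `samples` (n_iter x d),
#'   `log_post`, `accepted` (logical), `acceptance_rate`, `cov_final`
#' @export
dram_sample <- function(log_post, start, cov0, n_iter = 5000, seed = 1L,
                        adapt_interval = 500, dr_scale = 5, eps = 1e-10) {
  d <- length(start)
  set.seed(seed)
  C <- (cov0 + t(cov0)) / 2
  L <- tryCatch(chol(C), error = function(e)
    chol(C + diag(max(diag(C)) * 1e-8 + 1e-12, d)))
  samples <- matrix(NA_real_, n_iter, d)
  lp_tr <- numeric(n_iter)
  acc <- logical(n_iter)
  x <- as.numeric(start)
  lp_x <- log_post(x)
  if (!is.finite(lp_x)) stop("starting point has zero posterior mass")
  # log of the first-stage proposal density ratio terms used by DR
  ldmvn <- function(a, b, Li) {
    z <- backsolve(Li, a - b, transpose = TRUE)
    -0.5 * sum(z^2)
  }
  for (it in seq_len(n_iter)) {
    z <- as.numeric(t(L) %*% stats::rnorm(d))
    y1 <- x + z
    lp_y1 <- log_post(y1)
    a1 <- min(1, exp(lp_y1 - lp_x))
    if (is.finite(lp_y1) && stats::runif(1) < a1) {
      x <- y1; lp_x <- lp_y1; acc[it] <- TRUE
    } else {
      # delayed-rejection stage with a narrower proposal
      y2 <- x + as.numeric(t(L) %*% stats::rnorm(d)) / dr_scale
      lp_y2 <- log_post(y2)
      if (is.finite(lp_y2)) {
        a1_rev <- min(1, exp(lp_y1 - lp_y2))
        num <- lp_y2 + ldmvn(y1, y2, L) + log(pmax(1 - a1_rev, 1e-300))
        den <- lp_x + ldmvn(y1, x, L) + log(pmax(1 - a1, 1e-300))
        if (stats::runif(1) < exp(num - den)) {
          x <- y2; lp_x <- lp_y2; acc[it] <- TRUE
        }
      }
    }
    samples[it, ] <- x
    lp_tr[it] <- lp_x
    if (it %% adapt_interval == 0 && it >= max(2 * d, 100)) {
      Ck <- stats::cov(samples[seq_len(it), , drop = FALSE])
      C <- 2.38^2 / d * (Ck + eps * diag(d))
      L <- tryCatch(chol(C), error = function(e) L)
    }
  }
  if (!is.null(names(start))) colnames(samples) <- names(start)
  structure(list(samples = samples, log_post = lp_tr, accepted = acc,
                 acceptance_rate = mean(acc), cov_final = C, seed = seed,
                 n_iter = n_iter, adapt_interval = adapt_interval,
                 dr_scale = dr_scale),
            class = "cv_chain")
}

#' @export
print.cv_chain <- function(x, ...) {
  cat(sprintf("<cv_chain> %d iterations x %d parameters, acceptance %.1f%%\n",
              x$n_iter, ncol(x$samples), 100 * x$acceptance_rate))
  invisible(x)
}

#' Run DRAM on a synthetic dataset
#'
#' Posterior is the Gaussian likelihood of the dataset (noise variances
#' fixed at their generating values) times a bounded uniform prior;
#' simulation crashes are mapped to effectively zero posterior mass by
#' the crash guard, never aborting the chain.
#'
#' @param dataset a `cv_dataset`
#' @param subset inferred parameter names
#' @param params_ref `cv_params` carrying the fixed parameters
#' @param start list with `theta` and `cov` (from
#'   [initialize_starts()]); a bare numeric vector is also accepted
#' @param prior a `cv_prior` (defaults to +/-50% box)
#' @param n_iter,burn_in chain length and discarded prefix
#' @param seed RNG seed
#' @param init_state warm-start state for the simulator
#' @param ... further arguments to [dram_sample()]
#' @return a `cv_chain` with `burn_in`, `post` (post-burn-in samples)
#'   and the subset names attached
#' @export
run_dram <- function(dataset, subset, params_ref, start, prior = NULL,
                     n_iter = 5000, burn_in = 1000, seed = 1L,
                     init_state = NULL, ...) {
  params_ref <- .assert_params(params_ref)
  if (is.null(prior)) prior <- uniform_prior(params_ref, subset)
  if (is.null(init_state))
    init_state <- steady_state(params_ref, n_cycles = 30, rtol = 1e-6,
                               atol = 1e-6)
  llf <- .ll_factory(dataset, params_ref, subset, init_state)
  log_post <- function(th) {
    lp <- .log_prior(prior, th)
    if (!is.finite(lp)) return(-Inf)
    llf(th) + lp
  }
  if (is.numeric(start)) start <- list(theta = start, cov = NULL)
  theta0 <- setNames(as.numeric(start$theta), subset)
  # nudge boundary starts strictly inside the prior support
  width <- prior$upper - prior$lower
  theta0 <- pmin(pmax(theta0, prior$lower + 1e-6 * width),
                 prior$upper - 1e-6 * width)
  cov0 <- start$cov %||% diag((0.01 * abs(theta0))^2, length(theta0))
  ch <- dram_sample(log_post, theta0, cov0, n_iter = n_iter, seed = seed,
                    ...)
  ch$burn_in <- burn_in
  ch$subset <- subset
  ch$post <- ch$samples[(burn_in + 1):n_iter, , drop = FALSE]
  ch$design <- dataset$design$id
  ch
}

# stack post-burn-in samples from a list of chains into a 3-d array
.chain_array <- function(chains) {
  mats <- lapply(chains, function(ch)
    if (inherits(ch, "cv_chain")) ch$post %||% ch$samples else as.matrix(ch))
  n <- min(vapply(mats, nrow, integer(1)))
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  array(unlist(mats), dim = c(n, ncol(mats[[1]]), length(mats)),
        dimnames = list(NULL, colnames(mats[[1]]), NULL))
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Between/within-chain variance ratio for one parameter across
#' multiple chains of equal post-burn-in length.
#'
#' @param chains list of `cv_chain` objects (or matrices)
#' @param parameter column index or name
#' @return scalar PSRF (`NA` with a warning for degenerate chains)
#' @export
psrf <- function(chains, parameter = 1) {
  arr <- .chain_array(chains)
  x <- arr[, parameter, , drop = TRUE]
  if (is.null(dim(x))) x <- matrix(x, ncol = dim(arr)[3])
  n <- nrow(x); m <- ncol(x)
  stopifnot(m >= 2, n >= 2)
  means <- colMeans(x)
  W <- mean(apply(x, 2, stats::var))
  B <- n * stats::var(means)
  if (W <= 0) {
    warning("zero within-chain variance: PSRF degenerate")
    return(NA_real_)
  }
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

#' Multivariate potential scale reduction factor (Brooks-Gelman)
#'
#' @param chains list of `cv_chain` objects (or matrices)
#' @return scalar MPSRF
#' @export
mpsrf <- function(chains) {
  arr <- .chain_array(chains)
  n <- dim(arr)[1]; d <- dim(arr)[2]; m <- dim(arr)[3]
  stopifnot(m >= 2, n > d)
  W <- matrix(0, d, d)
  means <- matrix(NA_real_, m, d)
  for (j in seq_len(m)) {
    mj <- matrix(arr[, , j], ncol = d)
    W <- W + stats::cov(mj)
    means[j, ] <- colMeans(mj)
  }
  W <- W / m
  B_n <- stats::cov(means)  # = B / n
  Winv_B <- tryCatch(solve(W, B_n), error = function(e) NULL)
  if (is.null(Winv_B)) {
    warning("singular within-chain covariance: MPSRF degenerate")
    return(NA_real_)
  }
  lam <- max(Re(eigen(Winv_B, only.values = TRUE)$values))
  sqrt((n - 1) / n + (m + 1) / m * lam)
}

#' Convergence report for a set of chains
#'
#' @param chains list of `cv_chain`
#' @param cutoff PSRF/MPSRF convergence cutoff
#' @return object of class `cv_convergence`: per-parameter PSRF, MPSRF,
#'   median acceptance rate, pass flags
#' @export
convergence_report <- function(chains, cutoff = 1.1) {
  arr <- .chain_array(chains)
  pars <- dimnames(arr)[[2]] %||% paste0("theta", seq_len(dim(arr)[2]))
  ps <- vapply(seq_along(pars), function(j)
    suppressWarnings(psrf(chains, j)), numeric(1))
  names(ps) <- pars
  mp <- suppressWarnings(mpsrf(chains))
  acc <- stats::median(vapply(chains, function(ch)
    ch$acceptance_rate %||% NA_real_, numeric(1)), na.rm = TRUE)
  structure(list(psrf = ps, mpsrf = mp, median_acceptance = acc,
                 cutoff = cutoff,
                 pass = all(c(ps, mp) < cutoff, na.rm = TRUE)),
            class = "cv_convergence")
}

#' @export
print.cv_convergence <- function(x, ...) {
  cat("<cv_convergence> MPSRF", round(x$mpsrf, 3), "- median acceptance",
      sprintf("%.1f%%", 100 * x$median_acceptance), "\n")
  print(round(x$psrf, 3))
  cat(if (x$pass) "PASS" else "NOT CONVERGED", "at cutoff", x$cutoff, "\n")
  invisible(x)
}

#' Posterior summaries from MCMC chains
#'
#' @param chains list of `cv_chain` (post-burn-in samples pooled)
#' @param prior optional `cv_prior` used to flag posteriors whose 95%
#'   interval nearly fills the prior support (width ratio > 0.9)
#' @param level credible level
#' @return data frame with median, kernel-density MAP, equal-tailed
#'   interval; the pairwise correlation matrix is attached as an
#'   attribute `correlations`
#' @export
posterior_summaries <- function(chains, prior = NULL, level = 0.95) {
  arr <- .chain_array(chains)
  pooled <- do.call(rbind, lapply(seq_len(dim(arr)[3]),
                                  function(j) arr[, , j]))
  if (nrow(pooled) == 0) stop("empty chains")
  pars <- dimnames(arr)[[2]] %||% paste0("theta", seq_len(ncol(pooled)))
  colnames(pooled) <- pars
  a <- (1 - level) / 2
  summ <- do.call(rbind, lapply(seq_along(pars), function(j) {
    x <- pooled[, j]
    map <- if (stats::sd(x) == 0) x[1] else {
      dd <- stats::density(x)
      dd$x[which.max(dd$y)]
    }
    qs <- stats::quantile(x, c(a, 1 - a), names = FALSE)
    data.frame(param = pars[j], median = stats::median(x), map = map,
               lower = qs[1], upper = qs[2])
  }))
  if (!is.null(prior)) {
    pw <- prior$upper[summ$param] - prior$lower[summ$param]
    summ$width_ratio <- (summ$upper - summ$lower) / pw
    summ$flat_flag <- summ$width_ratio > 0.9
  }
  rownames(summ) <- NULL
  attr(summ, "correlations") <- suppressWarnings(stats::cor(pooled))
  summ
}
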