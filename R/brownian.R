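## Brownian-motion rate machinery: GLS likelihoods on phylogenetic
## covariance matrices, single-rate and state-dependent ("noncensored",
## regime-painted) maximum-likelihood fits, profile-likelihood CIs, and
## the single- vs multi-rate likelihood ratio test.

#' Per-state regime covariance matrices from a stochastic map
#'
#' Decomposes the phylogenetic covariance C into per-state components:
#' `C_k[i, j]` is the time the shared root-to-MRCA path of tips i and j
#' spends in state k under the map.  The components sum to C entrywise.
#'
#' @param map A `stoch_map` (or any list with `tree` and per-edge `maps`).
#' @param taxa Optional subset of tip labels to restrict the matrices to.
#' @return Named list of taxa x taxa matrices, one per state.
#' @export
regime_covariance <- function(map, taxa = NULL) {
  tree <- map$tree
  st <- state_times(map)
  states <- st$states
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  ## per-node per-state depth from the root
  depth <- matrix(0, n_all, length(states), dimnames = list(NULL, states))
  ord <- order_edges_preorder(tree)
  for (e in ord)
    depth[tree$edge[e, 2], ] <- depth[tree$edge[e, 1], ] + st$per_branch[e, ]
  anc <- ape::mrca(tree)
  keep <- if (is.null(taxa)) tree$tip.label else taxa
  ki <- match(keep, tree$tip.label)
  if (anyNA(ki)) stop("taxa not in map tree", call. = FALSE)
  out <- lapply(states, function(s) {
    M <- matrix(depth[anc[ki, ki, drop = FALSE], s], length(ki), length(ki),
                dimnames = list(keep, keep))
    M
  })
  names(out) <- states
  out
}

## Cholesky with escalating diagonal jitter for (near-)singular C, e.g.
## after zero-length polytomy branches.  Messages once per call chain.
safe_chol <- function(V, label = "covariance") {
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (!is.null(R)) return(list(R = R, jitter = 0))
  eps <- 1e-10 * mean(diag(V))
  for (k in 1:6) {
    R <- tryCatch(chol(V + diag(eps, nrow(V))), error = function(e) NULL)
    if (!is.null(R)) {
      message("singular ", label, " matrix: added diagonal jitter ",
              format(eps, digits = 3))
      return(list(R = R, jitter = eps))
    }
    eps <- eps * 100
  }
  stop("covariance matrix not positive definite even after jitter",
       call. = FALSE)
}

#' Brownian-motion log-likelihood on a phylogenetic covariance
#'
#' Multivariate normal log-density of tip values with mean `mu` and
#' covariance `sigma2 * C` (single rate) or `sum_k sigma2[k] * C[[k]]`
#' (state-dependent rates on regime components from
#' [regime_covariance()]).
#'
#' @param C A covariance matrix, or a named list of per-state matrices.
#' @param y Named numeric vector of trait values (order must match C).
#' @param sigma2 Scalar rate, or named vector matching `names(C)`.
#' @param mu Ancestral (root) mean.
#' @return Log-likelihood (scalar).
#' @export
bm_loglik <- function(C, y, sigma2, mu) {
  if (is.list(C)) {
    if (is.null(names(sigma2)) || !setequal(names(sigma2), names(C)))
      stop("sigma2 must be named to match the regime matrices",
           call. = FALSE)
    V <- Reduce(`+`, Map(function(s, M) s * M, sigma2[names(C)], C))
  } else {
    stopifnot(length(sigma2) == 1)
    V <- sigma2 * C
  }
  n <- length(y)
  if (nrow(V) != n) stop("dimension mismatch between C and y",
                         call. = FALSE)
  ch <- safe_chol(V)
  r <- y - mu
  z <- backsolve(ch$R, r, transpose = TRUE)
  -0.5 * n * log(2 * pi) - sum(log(diag(ch$R))) - 0.5 * sum(z^2)
}

## GLS mean and quadratic form given a Cholesky factor of V
gls_mean <- function(R, y) {
  one <- rep(1, length(y))
  z1 <- backsolve(R, one, transpose = TRUE)
  zy <- backsolve(R, y, transpose = TRUE)
  sum(z1 * zy) / sum(z1 * z1)
}

#' Single-rate Brownian motion fit
#'
#' Closed-form maximum likelihood under homogeneous Brownian motion:
#' `mu` is the phylogenetic GLS mean and
#' `sigma2 = (y - mu)' C^-1 (y - mu) / n` (ML convention, divisor n;
#' REML uses n - 1).
#'
#' @param tree A \code{phylo}, or a precomputed covariance matrix with
#'   dimnames.
#' @param y Named numeric vector of (complete) trait values; the tree is
#'   pruned to `names(y)` when needed.
#' @param method `"ML"` (default) or `"REML"`.
#' @return Object of class `rate_fit_single`: `sigma2`, `mu`, `loglik`,
#'   `n`, plus the covariance used (for profiling).
#' @export
fit_single_rate <- function(tree, y, method = c("ML", "REML")) {
  method <- match.arg(method)
  C <- tree_to_vcv(tree, names(y))
  y <- y[rownames(C)]
  n <- length(y)
  if (n < 2) stop("need at least 2 taxa", call. = FALSE)
  ch <- safe_chol(C)
  mu <- gls_mean(ch$R, y)
  z <- backsolve(ch$R, y - mu, transpose = TRUE)
  Q <- sum(z^2)
  div <- if (method == "ML") n else n - 1
  s2 <- Q / div
  if (s2 <= 0) {
    warning("zero variance in y: sigma2 = 0")
    s2 <- 0
  }
  ll <- if (s2 > 0)
    -0.5 * n * log(2 * pi * s2) - sum(log(diag(ch$R))) - 0.5 * Q / s2
  else Inf
  structure(list(sigma2 = s2, mu = mu, loglik = ll, n = n,
                 method = method, C = C, y = y,
                 logdetC = 2 * sum(log(diag(ch$R))), quad = Q),
            class = "rate_fit_single")
}

tree_to_vcv <- function(tree, taxa = NULL) {
  if (inherits(tree, "phylo")) {
    if (!is.null(taxa)) tree <- prune_to(tree, taxa)
    vcv_matrix(tree)
  } else {
    C <- as.matrix(tree)
    if (!is.null(taxa)) C <- C[taxa, taxa, drop = FALSE]
    C
  }
}

#' State-dependent Brownian motion fit on one stochastic map
#'
#' Joint maximum likelihood of per-state rates and the ancestral mean,
#' with the covariance `sum_k sigma2_k C_k` built from the map's regime
#' decomposition.  Optimization is over log-rates with the mean profiled
#' out by GLS at each step, multi-started from the single-rate estimate
#' and from it scaled by 0.25 and 4 to avoid ridge local optima.
#'
#' @param map A `stoch_map`.
#' @param y Named numeric vector of trait values; the regime matrices are
#'   restricted to `names(y)`.
#' @param expected_states Optional character vector; states expected to
#'   occur on the map (an absent one is an error).  A map carrying a
#'   single state degenerates to the single-rate fit.
#' @return Object of class `rate_fit_multi`: named `sigma2`, `mu`,
#'   `loglik`, `n`, `convergence`, plus regime matrices for profiling.
#' @export
fit_multi_rate <- function(map, y, expected_states = NULL) {
  Ck <- regime_covariance(map, names(y))
  states <- names(Ck)
  tot <- vapply(Ck, function(M) sum(diag(M)), numeric(1))
  Ck <- Ck[tot > 0]
  states <- names(Ck)
  if (!is.null(expected_states)) {
    absent <- setdiff(expected_states, states)
    if (length(absent))
      stop("state(s) absent from the map after pruning: ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  y <- y[rownames(Ck[[1]])]
  n <- length(y)
  single <- fit_single_rate(Reduce(`+`, Ck), y)
  s0 <- max(single$sigma2, 1e-12)
  negll <- function(lpar) {
    s2 <- stats::setNames(exp(lpar), states)
    V <- Reduce(`+`, Map(function(s, M) s * M, s2, Ck))
    ch <- tryCatch(safe_chol(V), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    mu <- gls_mean(ch$R, y)
    z <- backsolve(ch$R, y - mu, transpose = TRUE)
    0.5 * n * log(2 * pi) + sum(log(diag(ch$R))) + 0.5 * sum(z^2)
  }
  n_s <- length(states)
  starts <- list(rep(log(s0), n_s), rep(log(s0 / 4), n_s),
                 rep(log(4 * s0), n_s))
  if (n_s == 2)
    starts <- c(starts, list(log(c(s0 / 4, 4 * s0)),
                             log(c(4 * s0, s0 / 4))))
  best <- NULL
  for (st in starts) {
    opt <- suppressMessages(
      stats::optim(st, negll, method = "L-BFGS-B",
                   lower = log(1e-10), upper = log(1e6),
                   control = list(factr = 1e4)))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  s2 <- stats::setNames(exp(best$par), states)
  V <- Reduce(`+`, Map(function(s, M) s * M, s2, Ck))
  ch <- suppressMessages(safe_chol(V))
  mu <- gls_mean(ch$R, y)
  ll <- -best$value
  ## nesting guard: the multi-rate optimum can never fall below the
  ## single-rate optimum (equal rates are in the parameter space)
  if (ll < single$loglik) {
    eq <- negll(rep(log(s0), n_s))
    if (-eq > ll) {
      s2 <- stats::setNames(rep(s0, n_s), states)
      ll <- -eq
      mu <- single$mu
    }
  }
  structure(list(sigma2 = s2, mu = mu, loglik = ll, n = n,
                 convergence = best$convergence == 0,
                 states = states, Ck = Ck, y = y,
                 single = single),
            class = "rate_fit_multi")
}

#' Likelihood ratio test: single- vs state-dependent Brownian motion
#'
#' `chisq = 2 (lnL_multi - lnL_single)`, clipped at 0, compared to a
#' chi-square with `df = n_states - 1`.
#'
#' @param multi A `rate_fit_multi`.
#' @param single A `rate_fit_single` on the same data (defaults to the
#'   one embedded in `multi`).
#' @return List: `chisq`, `df`, `p`.
#' @export
lrt_single_vs_multi <- function(multi, single = multi$single) {
  df <- length(multi$sigma2) - 1L
  chisq <- max(0, 2 * (multi$loglik - single$loglik))
  list(chisq = chisq, df = df,
       p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Profile-likelihood confidence interval for Brownian rates
#'
#' For each rate parameter, the interval is the set of values whose
#' profile log-likelihood (all other parameters re-optimized) is within
#' `qchisq(level, 1) / 2` of the maximum.  Endpoints that never cross the
#' threshold within a wide search bracket are reported as 0 / `Inf`.
#'
#' @param fit A `rate_fit_single` or `rate_fit_multi`.
#' @param level Confidence level (default 0.95).
#' @return For single fits a length-2 vector; for multi fits a matrix with
#'   one row per state (`lo`, `hi` columns).
#' @export
rate_ci <- function(fit, level = 0.95) {
  thr <- stats::qchisq(level, 1) / 2
  if (inherits(fit, "rate_fit_single")) {
    ## closed-form profile: mu-hat does not depend on sigma2
    n <- fit$n; Q <- fit$quad; ld <- fit$logdetC
    prof <- function(s2) -0.5 * n * log(2 * pi * s2) - 0.5 * ld -
      0.5 * Q / s2
    return(profile_interval(prof, fit$sigma2, fit$loglik, thr))
  }
  stopifnot(inherits(fit, "rate_fit_multi"))
  states <- fit$states
  out <- matrix(NA_real_, length(states), 2,
                dimnames = list(states, c("lo", "hi")))
  for (k in seq_along(states)) {
    prof <- profile_multi_fun(fit, k)
    out[k, ] <- profile_interval(prof, fit$sigma2[k], fit$loglik, thr)
  }
  out
}

## profile log-likelihood of sigma2[k] with the other rate and mu
## re-optimized
profile_multi_fun <- function(fit, k) {
  Ck <- fit$Ck; y <- fit$y; n <- fit$n
  other <- setdiff(seq_along(Ck), k)
  force(k)
  function(s2k) {
    g <- function(ls_other) {
      s2 <- numeric(length(Ck))
      s2[k] <- s2k; s2[other] <- exp(ls_other)
      V <- Reduce(`+`, Map(`*`, as.list(s2), Ck))
      ch <- tryCatch(suppressMessages(safe_chol(V)),
                     error = function(e) NULL)
      if (is.null(ch)) return(-1e10)
      mu <- gls_mean(ch$R, y)
      z <- backsolve(ch$R, y - mu, transpose = TRUE)
      -0.5 * n * log(2 * pi) - sum(log(diag(ch$R))) - 0.5 * sum(z^2)
    }
    s_start <- log(max(fit$sigma2[other], 1e-10))
    opt <- stats::optimize(g, c(s_start - 8, s_start + 8), maximum = TRUE,
                           tol = 1e-4)
    opt$objective
  }
}

## find {s : 2 (llmax - prof(s)) <= 2 thr} by bisection on each side
profile_interval <- function(prof, s_hat, llmax, thr) {
  target <- function(s) (llmax - prof(s)) - thr
  lo <- s_hat; f_lo <- -thr
  s <- max(s_hat, 1e-12)
  lower <- s; found <- FALSE
  for (k in 1:60) {
    lower <- lower / 2
    if (target(lower) > 0) { found <- TRUE; break }
  }
  lo <- if (found)
    stats::uniroot(target, c(lower, s), tol = s * 1e-6)$root else 0
  upper <- s; found <- FALSE
  for (k in 1:60) {
    upper <- upper * 2
    if (target(upper) > 0) { found <- TRUE; break }
  }
  hi <- if (found)
    stats::uniroot(target, c(s, upper), tol = upper * 1e-8)$root else Inf
  c(lo = lo, hi = hi)
}

#' Pool state-dependent rate fits over a stochastic-map ensemble
#'
#' Fits the state-dependent Brownian model on every map in the ensemble
#' and integrates over mapping uncertainty: point estimates and
#' log-likelihoods are across-map means (with SDs reported), and the
#' confidence interval is computed on the pooled profile — the across-map
#' mean of the per-map profile log-likelihood curves on a common rate
#' grid.  The single-rate fit does not depend on the map (the regime
#' components always sum to the same C) and is computed once.
#'
#' @param ensemble A `map_ensemble`.
#' @param y Named numeric vector of trait values.
#' @param level CI level.
#' @param grid_size Number of rate-grid points per state for the pooled
#'   profile.
#' @return Object of class `rate_fit_pooled`: `sigma2` (across-map mean
#'   per state), `sigma2_sd`, `loglik` (mean multi-rate lnL), `single`
#'   (the shared single-rate fit), `lrt`, `ci` (per-state matrix),
#'   `n_maps`, `n_failed`, `per_map` (matrix of per-map estimates).
#' @export
pool_over_maps <- function(ensemble, y, level = 0.95, grid_size = 31) {
  stopifnot(inherits(ensemble, "map_ensemble"),
            length(ensemble$maps) >= 1)
  fits <- vector("list", length(ensemble$maps))
  failed <- logical(length(fits))
  for (i in seq_along(fits)) {
    fits[[i]] <- tryCatch(fit_multi_rate(ensemble$maps[[i]], y),
                          error = function(e) {
                            warning("map ", i, " failed to fit: ",
                                    conditionMessage(e))
                            NULL
                          })
    failed[i] <- is.null(fits[[i]])
  }
  fits <- fits[!failed]
  if (!length(fits)) stop("every map failed to fit", call. = FALSE)
  states <- fits[[1]]$states
  per_map <- t(vapply(fits, function(f) f$sigma2, numeric(length(states))))
  colnames(per_map) <- states
  s2_mean <- colMeans(per_map)
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  single <- fits[[1]]$single
  ## pooled profile CI: mean of per-map relative profile curves
  thr <- stats::qchisq(level, 1) / 2
  ci <- matrix(NA_real_, length(states), 2,
               dimnames = list(states, c("lo", "hi")))
  for (k in seq_along(states)) {
    center <- s2_mean[k]
    grid <- exp(seq(log(center / 30), log(center * 30),
                    length.out = grid_size))
    rel <- matrix(NA_real_, length(fits), grid_size)
    for (i in seq_along(fits)) {
      pf <- profile_multi_fun(fits[[i]], k)
      rel[i, ] <- vapply(grid, pf, numeric(1)) - fits[[i]]$loglik
    }
    avg <- colMeans(rel)
    ok <- which(max(avg) - avg <= thr)
    ci[k, ] <- c(grid[min(ok)], grid[max(ok)])
  }
  lrt <- {
    chisq <- max(0, 2 * (mean(lls) - single$loglik))
    list(chisq = chisq, df = length(states) - 1L,
         p = stats::pchisq(chisq, length(states) - 1L,
                           lower.tail = FALSE))
  }
  structure(list(sigma2 = s2_mean,
                 sigma2_sd = apply(per_map, 2, stats::sd),
                 loglik = mean(lls), single = single, lrt = lrt,
                 ci = ci, n_maps = length(fits),
                 n_failed = sum(failed), per_map = per_map,
                 n = fits[[1]]$n, level = level),
            class = "rate_fit_pooled")
}

#' Prepare a trait for rate / signal analysis
#'
#' Natural-log transform (only when every value is strictly positive, or
#' when forced) followed by a z-score across the analyzed species set.
#' Both steps are flagged in attributes so reports can state the scale.
#'
#' @param x Named numeric vector (NAs dropped).
#' @param log_transform `"auto"` (log iff all positive), `"yes"`, `"no"`.
#' @param standardize Z-score after any log step (default `TRUE`).
#' @return Transformed named vector with attributes `logged` and
#'   `standardized`.
#' @export
prep_trait <- function(x, log_transform = c("auto", "yes", "no"),
                       standardize = TRUE) {
  log_transform <- match.arg(log_transform)
  x <- x[!is.na(x)]
  logged <- switch(log_transform,
                   auto = all(x > 0),
                   yes = TRUE,
                   no = FALSE)
  if (logged) {
    if (any(x <= 0))
      stop("log transform requested but values are not all positive",
           call. = FALSE)
    x <- log(x)
  }
  if (standardize) {
    s <- stats::sd(x)
    x <- if (s > 0) (x - mean(x)) / s else x - mean(x)
  }
  attr(x, "logged") <- logged
  attr(x, "standardized") <- standardize
  x
}
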