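## Phylogenetic signal: independent contrasts, Blomberg's K with a
## tip-shuffling permutation test on contrast variance, and Pagel's
## lambda with a likelihood ratio test against lambda = 1.

#' Phylogenetically independent contrasts
#'
#' Felsenstein's pruning recursion: at each internal node of a binary
#' tree the standardized contrast is
#' `(x_left - x_right) / sqrt(v_left + v_right)`, the node value is the
#' variance-weighted average of its daughters, and the node's own branch
#' is lengthened by `v_l v_r / (v_l + v_r)`.  Zero-length daughter pairs
#' (typical after random polytomy resolution) would give undefined
#' contrasts, so zero branches are jittered by `1e-8 * tree depth`
#' (logged via `message()`).
#'
#' @param tree A binary \code{phylo} (use [resolve_polytomies()] first).
#' @param y Named numeric vector of complete trait values for every tip.
#' @param jitter_zero Jitter zero-length branches (default `TRUE`; if
#'   `FALSE`, a node with zero combined daughter variance is an error).
#' @return List of class `contrast_set`: `contrasts` (n - 1 standardized
#'   contrasts, named by internal node label), `variances` (expected
#'   variance, the sum of adjusted daughter branch lengths), `root_value`,
#'   `root_variance` (adjusted branch-length sum at the root).
#' @export
pic_contrasts <- function(tree, y, jitter_zero = TRUE) {
  prep <- pic_prepare(tree, y, jitter_zero)
  n_tip <- length(tree$tip.label)
  x <- numeric(n_tip + tree$Nnode)
  x[seq_len(n_tip)] <- prep$y
  contrasts <- variances <- numeric(tree$Nnode)
  vadj <- prep$vadj
  for (i in seq_along(prep$post)) {
    v <- prep$post[i]
    kids <- prep$children[[v]]
    vs <- vadj[kids]
    x[v] <- sum(x[kids] / vs) / sum(1 / vs)
    contrasts[v - n_tip] <- (x[kids[1]] - x[kids[2]]) / sqrt(sum(vs))
    variances[v - n_tip] <- sum(vs)
    vadj[v] <- vadj[v] + prod(vs) / sum(vs)
  }
  labs <- if (!is.null(tree$node.label)) tree$node.label else
    as.character((n_tip + 1L):(n_tip + tree$Nnode))
  root <- n_tip + 1L
  structure(list(contrasts = stats::setNames(contrasts, labs),
                 variances = stats::setNames(variances, labs),
                 root_value = x[root],
                 root_variance = vadj[root] - tree_root_edge(tree)),
            class = "contrast_set")
}

tree_root_edge <- function(tree) if (is.null(tree$root.edge)) 0 else
  tree$root.edge

## shared validation + per-node adjusted branch lengths scaffold
pic_prepare <- function(tree, y, jitter_zero) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.binary(tree))
    stop("tree must be binary; resolve polytomies first", call. = FALSE)
  if (!all(tree$tip.label %in% names(y)))
    stop("y must cover every tip", call. = FALSE)
  yv <- as.numeric(y[tree$tip.label])
  if (anyNA(yv)) stop("y contains missing values", call. = FALSE)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  elen <- numeric(n_all)
  elen[tree$edge[, 2]] <- tree$edge.length
  if (any(tree$edge.length == 0)) {
    if (!jitter_zero)
      stop("zero-length branches give undefined contrasts; enable ",
           "jitter_zero or adjust the tree", call. = FALSE)
    eps <- 1e-8 * max(node_depths(tree))
    zero <- tree$edge[, 2][tree$edge.length == 0]
    elen[zero] <- eps
    message("jittered ", length(zero),
            " zero-length branch(es) by ", format(eps, digits = 3),
            " for contrast calculation")
  }
  post <- rev(preorder_nodes(tree))       # children before parents
  list(y = yv, vadj = elen, post = post,
       children = children_list(tree))
}

## Contrasts are linear in y: return the (n-1) x n operator matrix and
## the contrast variances.  Used to vectorize the permutation test.
pic_operator <- function(tree, jitter_zero = TRUE) {
  n_tip <- length(tree$tip.label)
  dummy <- stats::setNames(numeric(n_tip), tree$tip.label)
  prep <- suppressMessages(pic_prepare(tree, dummy, jitter_zero))
  Xc <- matrix(0, n_tip + tree$Nnode, n_tip)   # node value coefficients
  Xc[cbind(seq_len(n_tip), seq_len(n_tip))] <- 1
  L <- matrix(0, tree$Nnode, n_tip)
  variances <- numeric(tree$Nnode)
  vadj <- prep$vadj
  for (i in seq_along(prep$post)) {
    v <- prep$post[i]
    kids <- prep$children[[v]]
    vs <- vadj[kids]
    w <- (1 / vs) / sum(1 / vs)
    Xc[v, ] <- w[1] * Xc[kids[1], ] + w[2] * Xc[kids[2], ]
    L[v - n_tip, ] <- (Xc[kids[1], ] - Xc[kids[2], ]) / sqrt(sum(vs))
    variances[v - n_tip] <- sum(vs)
    vadj[v] <- vadj[v] + prod(vs) / sum(vs)
  }
  colnames(L) <- tree$tip.label
  list(L = L, variances = variances)
}

#' Blomberg's K statistic of phylogenetic signal
#'
#' Ratio of the observed to the Brownian-expected ratio of trait variance
#' to phylogenetically corrected variance:
#' `K = (MSE0 / MSE) / ((tr(C) - n / sum(C^-1)) / (n - 1))`,
#' where `MSE0` uses raw deviations from the phylogenetic GLS mean and
#' `MSE` is the C-whitened mean square.  `K = 1` is the Brownian
#' expectation; `K > 1` means close relatives are more similar than
#' Brownian motion predicts, `K < 1` less similar.  On a star phylogeny
#' with equal depths K is identically 1.
#'
#' @param tree A \code{phylo} (pruned to `names(y)` if needed).
#' @param y Named numeric vector of complete trait values.
#' @return Scalar K (>= 0).
#' @export
blomberg_k <- function(tree, y) {
  C <- tree_to_vcv(tree, names(y))
  y <- y[rownames(C)]
  n <- length(y)
  ch <- safe_chol(C, label = "phylogenetic covariance")
  one <- rep(1, n)
  z1 <- backsolve(ch$R, one, transpose = TRUE)
  zy <- backsolve(ch$R, y, transpose = TRUE)
  a_hat <- sum(z1 * zy) / sum(z1^2)
  r <- y - a_hat
  mse0 <- sum(r^2) / (n - 1)
  zr <- backsolve(ch$R, r, transpose = TRUE)
  mse <- sum(zr^2) / (n - 1)
  expected <- (sum(diag(C)) - n / sum(z1^2)) / (n - 1)
  (mse0 / mse) / expected
}

#' Permutation test for phylogenetic signal via contrast variance
#'
#' The observed statistic is the variance of the standardized independent
#' contrasts; under tip-shuffling randomization of the trait values the
#' contrast variance rises when real signal is destroyed, so the test is
#' one-sided: `p = (#\{null <= observed\} + 1) / (n_perm + 1)` (low
#' contrast variance = signal; floor `1 / (n_perm + 1)`).  Contrasts are
#' linear in the tip values, so the null is computed by one matrix
#' product over all permutations.
#'
#' @param tree A binary \code{phylo}; pruned to `names(y)` as needed.
#' @param y Named numeric vector of complete trait values.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed.
#' @return List: `obs` (contrast variance), `p`, `n_perm`, `seed`.
#' @export
k_permutation_test <- function(tree, y, n_perm = 1000, seed = 1L) {
  if (inherits(tree, "phylo") &&
      length(tree$tip.label) > length(y))
    tree <- prune_to(tree, names(y))
  op <- pic_operator(tree)
  yv <- as.numeric(y[tree$tip.label])
  obs <- stats::var(as.vector(op$L %*% yv))
  null <- with_local_seed(seed, {
    P <- vapply(seq_len(n_perm), function(i) yv[sample.int(length(yv))],
                numeric(length(yv)))
    cn <- op$L %*% P
    apply(cn, 2, stats::var)
  })
  list(obs = obs, p = (sum(null <= obs) + 1) / (n_perm + 1),
       n_perm = n_perm, seed = seed)
}

#' Pagel's lambda by maximum likelihood
#'
#' The lambda transform multiplies the off-diagonal entries of the
#' phylogenetic covariance by `lambda`, leaving tip variances unchanged;
#' `lambda = 1` is untransformed Brownian motion and `lambda = 0` a star
#' phylogeny (no covariance).  For fixed lambda the rate and ancestral
#' mean have closed-form GLS solutions, so lambda is found by 1-D profile
#' maximization on `[0, lambda_max]` (default `lambda_max = 1`, the
#' feasible range on ultrametric trees; values above 1 can make the
#' transformed covariance indefinite).  Both endpoint likelihoods are
#' also evaluated so boundary optima are never missed.
#'
#' @param tree A \code{phylo} (pruned to `names(y)` if needed).
#' @param y Named numeric vector of complete trait values.
#' @param lambda_max Upper end of the search bracket (default 1).
#' @return List of class `lambda_fit`: `lambda`, `loglik` (at the MLE),
#'   `loglik_1` (at lambda = 1), `sigma2`, `mu`, `boundary` (`"none"`,
#'   `"lower"` or `"upper"`), `n`.
#' @export
pagel_lambda <- function(tree, y, lambda_max = 1) {
  C <- tree_to_vcv(tree, names(y))
  y <- y[rownames(C)]
  n <- length(y)
  offdiag <- C - diag(diag(C))
  ll_at <- function(lam) {
    Cl <- diag(diag(C)) + lam * offdiag
    R <- tryCatch(chol(Cl), error = function(e) NULL)
    if (is.null(R) && lam <= 1) {
      ## legitimately singular C (e.g. zero-length resolution branches):
      ## fall back to the jittered factorization
      ch <- tryCatch(suppressMessages(safe_chol(Cl)),
                     error = function(e) NULL)
      if (!is.null(ch)) R <- ch$R
    }
    if (is.null(R)) return(list(ll = -Inf))   # beyond the PD limit
    ch <- list(R = R)
    mu <- gls_mean(ch$R, y)
    z <- backsolve(ch$R, y - mu, transpose = TRUE)
    Q <- sum(z^2)
    s2 <- Q / n
    if (s2 <= 0) return(list(ll = -Inf, s2 = 0, mu = mu))
    list(ll = -0.5 * n * log(2 * pi * s2) - sum(log(diag(ch$R))) -
           0.5 * n, s2 = s2, mu = mu)
  }
  opt <- stats::optimize(function(l) ll_at(l)$ll, c(0, lambda_max),
                         maximum = TRUE, tol = 1e-8)
  cand <- list(c(opt$maximum, opt$objective),
               c(0, ll_at(0)$ll),
               c(lambda_max, ll_at(lambda_max)$ll))
  best <- cand[[which.max(vapply(cand, `[`, numeric(1), 2))]]
  lam <- best[1]
  at <- ll_at(lam)
  tol_b <- 1e-6 * lambda_max
  boundary <- if (lam <= tol_b) "lower" else
    if (lam >= lambda_max - tol_b) "upper" else "none"
  structure(list(lambda = lam, loglik = best[2],
                 loglik_1 = ll_at(1)$ll, sigma2 = at$s2, mu = at$mu,
                 boundary = boundary, n = n),
            class = "lambda_fit")
}

#' Likelihood ratio test of lambda against 1
#'
#' `chisq = 2 (lnL(lambda_hat) - lnL(1))`, clipped at 0, against
#' chi-square with 1 df.  When the estimate sits on a bracket boundary
#' the test is conservative; the boundary is reported alongside p.
#'
#' @param fit A `lambda_fit` from [pagel_lambda()].
#' @return List: `chisq`, `p`, `boundary`.
#' @export
lambda_lrt <- function(fit) {
  stopifnot(inherits(fit, "lambda_fit"))
  chisq <- max(0, 2 * (fit$loglik - fit$loglik_1))
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE),
       boundary = fit$boundary)
}

#' All phylogenetic-signal statistics for one trait / group
#'
#' Runs [blomberg_k()], [k_permutation_test()], [pagel_lambda()] and
#' [lambda_lrt()] on the tree pruned to the species with trait values.
#'
#' @param tree A \code{phylo} covering at least `names(y)`.
#' @param y Named numeric vector (NAs dropped).
#' @param n_perm Permutations for the K test.
#' @param seed Integer seed.
#' @return List of class `signal_result`: `K`, `p_K`, `lambda`,
#'   `loglik_lambda`, `loglik_1`, `p_lambda`, `boundary`, `n`, `n_perm`,
#'   `seed`.
#' @export
signal_tests <- function(tree, y, n_perm = 1000, seed = 1L) {
  y <- y[!is.na(y)]
  if (length(y) < 4)
    stop("need at least 4 species with trait values", call. = FALSE)
  pruned <- prune_to(tree, names(y))
  K <- blomberg_k(pruned, y)
  kt <- k_permutation_test(pruned, y, n_perm = n_perm, seed = seed)
  lf <- pagel_lambda(pruned, y)
  lt <- lambda_lrt(lf)
  structure(list(K = K, p_K = kt$p, lambda = lf$lambda,
                 loglik_lambda = lf$loglik, loglik_1 = lf$loglik_1,
                 p_lambda = lt$p, boundary = lf$boundary,
                 n = length(y), n_perm = n_perm, seed = seed),
            class = "signal_result")
}
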