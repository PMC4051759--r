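## Two-state continuous-time Markov machinery for the growth-form
## character.  Transition probabilities use the closed form
##   P(t) = Pi + (I - Pi) * exp(-s t),  s = q12 + q21,
## where Pi has the stationary distribution in each row.

mk_pmat <- function(q12, q21, t) {
  s <- q12 + q21
  if (s <= 0) return(diag(2))
  pi2 <- q12 / s                     # stationary mass of state 2
  e <- exp(-s * t)
  matrix(c(1 - pi2 + pi2 * e, 1 - pi2 - (1 - pi2) * e,
           pi2 - pi2 * e,      pi2 + (1 - pi2) * e),
         2, 2)                       # [i, j] = P(i -> j in t)
}

mk_stationary <- function(q12, q21) {
  s <- q12 + q21
  if (s <= 0) return(c(0.5, 0.5))
  c(q21, q12) / s
}

## Scaled Felsenstein pruning.  Returns per-node conditional likelihoods
## (rows normalized) and the total log-likelihood.
mk_prune <- function(tree, tip_states, q12, q21, prior, states) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  idx <- match(tip_states[tree$tip.label], states)
  if (anyNA(idx))
    stop("tip state not in model states {",
         paste(states, collapse = ", "), "}: ",
         paste(unique(tip_states[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  L <- matrix(0, n_all, 2)
  L[cbind(seq_len(n_tip), idx)] <- 1
  L[(n_tip + 1L):n_all, ] <- 1
  logscale <- 0
  ord <- rev(order_edges_preorder(tree))   # postorder over edges
  for (e in ord) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    P <- mk_pmat(q12, q21, tree$edge.length[e])
    contrib <- as.vector(P %*% L[ch, ])
    L[p, ] <- L[p, ] * contrib
    m <- max(L[p, ])
    if (m > 0 && (m < 1e-12 || m > 1e12)) {
      L[p, ] <- L[p, ] / m
      logscale <- logscale + log(m)
    }
  }
  root <- n_tip + 1L
  lik <- sum(prior * L[root, ])
  if (lik <= 0) return(list(L = L, loglik = -Inf))
  list(L = L, loglik = log(lik) + logscale)
}

#' Log-likelihood of tip states under a 2-state Markov model
#'
#' Exact pruning-algorithm likelihood of a binary character on a
#' calibrated tree, with transition probabilities from the closed-form
#' 2-state matrix exponential.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param tip_states Named character vector (names = tip labels).
#' @param q12,q21 Transition rates state 1 -> 2 and 2 -> 1 (per Myr).
#' @param prior Root-state prior (2-vector summing to 1); default the
#'   stationary distribution of the rate matrix.
#' @param states The two state labels, in rate-matrix order.
#' @return Log-likelihood (scalar).
#' @export
mk_loglik <- function(tree, tip_states, q12, q21 = q12,
                      prior = mk_stationary(q12, q21),
                      states = c("liana", "tree")) {
  stopifnot(inherits(tree, "phylo"), q12 >= 0, q21 >= 0,
            length(prior) == 2, abs(sum(prior) - 1) < 1e-8)
  if (!all(tree$tip.label %in% names(tip_states)))
    stop("tip_states must cover every tip label", call. = FALSE)
  mk_prune(tree, tip_states, q12, q21, prior, states)$loglik
}

#' Fit a 2-state Mk model by maximum likelihood
#'
#' Equal-rates (`"ER"`, one parameter, the default — minimal and
#' identifiable at the ~134-species scale this pipeline targets) or
#' all-rates-different (`"ARD"`, two parameters) fit of the growth-form
#' transition rate(s), maximizing [mk_loglik()] over log-rates.  The root
#' prior is the stationary distribution of the fitted rate matrix.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param tip_states Named character vector of states at the tips.
#' @param model_form `"ER"` or `"ARD"`.
#' @param states The two state labels.
#' @return An object of class `mk_model`: `states`, `Q` (2x2 rate
#'   matrix), `prior`, `loglik`, `model_form`, `convergence` (TRUE/FALSE).
#' @export
fit_mk <- function(tree, tip_states, model_form = c("ER", "ARD"),
                   states = c("liana", "tree")) {
  model_form <- match.arg(model_form)
  present <- unique(tip_states[tree$tip.label])
  if (length(setdiff(states, present)) > 0)
    stop("rate not identifiable: only state(s) {",
         paste(present, collapse = ", "), "} present among tips",
         call. = FALSE)
  lo <- log(1e-7); hi <- log(1e3)
  if (model_form == "ER") {
    f <- function(lq) mk_loglik(tree, tip_states, exp(lq), exp(lq),
                                prior = c(0.5, 0.5), states = states)
    opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
    q12 <- q21 <- exp(opt$maximum)
    ll <- opt$objective
    conv <- TRUE
  } else {
    f <- function(lq) -mk_loglik(tree, tip_states, exp(lq[1]), exp(lq[2]),
                                 states = states)
    opt <- stats::optim(c(log(0.01), log(0.01)), f, method = "L-BFGS-B",
                        lower = lo, upper = hi)
    q12 <- exp(opt$par[1]); q21 <- exp(opt$par[2])
    ll <- -opt$value
    conv <- opt$convergence == 0
  }
  Q <- matrix(c(-q12, q21, q12, -q21), 2, 2,
              dimnames = list(states, states))
  structure(list(states = states, Q = Q,
                 prior = mk_stationary(q12, q21), loglik = ll,
                 model_form = model_form, convergence = conv),
            class = "mk_model")
}

## Marginal root-state probabilities given tips (used by tests and for
## reporting).
mk_root_marginal <- function(tree, tip_states, model) {
  q12 <- model$Q[1, 2]; q21 <- model$Q[2, 1]
  pr <- mk_prune(tree, tip_states, q12, q21, model$prior, model$states)
  root <- length(tree$tip.label) + 1L
  w <- model$prior * pr$L[root, ]
  w / sum(w)
}

#' Sample stochastic character maps
#'
#' Draws fully timed state histories of the growth-form character from
#' its posterior distribution given the tip states and a fitted Mk model:
#' node states are sampled from their joint conditional distribution by
#' backward filtering / forward sampling on the pruning recursion, then
#' each branch's internal history is drawn conditional on its endpoint
#' states by rejection sampling of forward Markov paths (a path is
#' resampled until its end state matches the sampled child state, up to
#' `max_reject` attempts per branch).
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param model A fitted [fit_mk()] model.
#' @param tip_states Named character vector of tip states.
#' @param n_maps Number of maps to draw (>= 1, default 100).
#' @param seed Integer seed; the ensemble is reproducible.
#' @param max_reject Attempt bound per branch before erroring.
#' @return An object of class `map_ensemble`: `tree`, `maps` (list of
#'   `stoch_map`, each with per-edge segment vectors as in
#'   [simulate_discrete()], sampled `node_states`, and the log-probability
#'   of the node-state assignment), `model`, `seed`.
#' @export
sample_stochastic_maps <- function(tree, model, tip_states, n_maps = 100,
                                   seed = 1L, max_reject = 10000L) {
  stopifnot(inherits(model, "mk_model"), n_maps >= 1)
  q12 <- model$Q[1, 2]; q21 <- model$Q[2, 1]
  states <- model$states
  leave <- c(q12, q21)                       # leave rate per state index
  pr <- mk_prune(tree, tip_states, q12, q21, model$prior, states)
  if (!is.finite(pr$loglik))
    stop("tip states have zero likelihood under the model", call. = FALSE)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  ord <- order_edges_preorder(tree)
  with_local_seed(seed, {
    maps <- vector("list", n_maps)
    for (m in seq_len(n_maps)) {
      st <- integer(n_tip + tree$Nnode)
      w <- model$prior * pr$L[root, ]
      st[root] <- sample.int(2L, 1L, prob = w)
      logp <- log(w[st[root]] / sum(w))
      segs <- vector("list", nrow(tree$edge))
      for (e in ord) {
        p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        t_e <- tree$edge.length[e]
        P <- mk_pmat(q12, q21, t_e)
        w <- P[st[p], ] * pr$L[ch, ]
        st[ch] <- sample.int(2L, 1L, prob = w)
        logp <- logp + log(P[st[p], st[ch]])
        segs[[e]] <- sample_branch_path(st[p], st[ch], t_e, leave,
                                        states, max_reject)
      }
      maps[[m]] <- structure(
        list(tree = tree, maps = segs,
             node_states = states[st], log_prob = logp),
        class = "stoch_map")
    }
    structure(list(tree = tree, maps = maps, model = model, seed = seed),
              class = "map_ensemble")
  })
}

## Endpoint-conditioned 2-state path on one branch, by rejection.
sample_branch_path <- function(s_from, s_to, t_e, leave, states,
                               max_reject) {
  if (t_e <= 0) {
    if (s_from != s_to)
      stop("zero-length branch with differing endpoint states",
           call. = FALSE)
    return(stats::setNames(0, states[s_from]))
  }
  for (k in seq_len(max_reject)) {
    cur <- s_from; rem <- t_e
    durs <- numeric(0); labs <- integer(0)
    repeat {
      w <- if (leave[cur] > 0) stats::rexp(1, leave[cur]) else Inf
      if (w >= rem) {
        durs <- c(durs, rem); labs <- c(labs, cur)
        break
      }
      durs <- c(durs, w); labs <- c(labs, cur)
      rem <- rem - w
      cur <- 3L - cur
    }
    if (cur == s_to) return(stats::setNames(durs, states[labs]))
  }
  stop("endpoint-conditioned path rejected ", max_reject,
       " times on a branch (rate too small for differing endpoints); ",
       "consider a larger transition rate", call. = FALSE)
}

#' Time spent in each state, per branch and in total
#'
#' Collapses a stochastic map (or a true simulated history) to per-branch
#' durations per state.  Per branch the durations sum exactly to the
#' branch length.
#'
#' @param map A `stoch_map`, or a list with elements `tree` and `maps`
#'   (per-edge named duration vectors).
#' @return List: `per_branch` (edge x state matrix of durations),
#'   `total` (named vector of per-state totals), `states`.
#' @export
state_times <- function(map) {
  tree <- map$tree
  segs <- map$maps
  states <- sort(unique(unlist(lapply(segs, names))))
  per <- matrix(0, nrow(tree$edge), length(states),
                dimnames = list(NULL, states))
  for (e in seq_along(segs)) {
    s <- segs[[e]]
    for (st in unique(names(s)))
      per[e, st] <- sum(s[names(s) == st])
  }
  list(per_branch = per, total = colSums(per), states = states)
}

#' Serialize a map ensemble to JSON lines
#'
#' One line per map: a JSON object mapping branch id
#' (`"parent-child"` node numbers) to its ordered `[state, duration]`
#' segment list, preceded by the sampled node states and log-probability.
#'
#' @param ensemble A `map_ensemble`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_map_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "map_ensemble"))
  con <- file(path, "w")
  on.exit(close(con))
  edge <- ensemble$tree$edge
  ids <- paste0(edge[, 1], "-", edge[, 2])
  for (m in ensemble$maps) {
    branches <- stats::setNames(lapply(seq_along(m$maps), function(e) {
      s <- m$maps[[e]]
      lapply(seq_along(s), function(i) list(state = names(s)[i],
                                            duration = unname(s[i])))
    }), ids)
    writeLines(jsonlite::toJSON(list(log_prob = m$log_prob,
                                     branches = branches),
                                auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}
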