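## Independent oracle implementations used to cross-check the package.
## Each is deliberately written with a different algorithmic route than
## the implementation it checks.

## BLADJ oracle: per-node breadth-first walking, no shared recursion
## with bladj_smooth().  Same definition: nearest constrained ancestor,
## nearest constrained descendant (ties -> oldest; tips are age-0
## constraints; search stops at constrained nodes), linear interpolation
## by topological distance, then preorder clamp to the parent age.
oracle_bladj_ages <- function(tree, ages) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  par <- lianevol:::parent_vec(tree)
  kids <- lianevol:::children_list(tree)
  fixed <- rep(NA_real_, n_all)
  fixed[seq_len(n_tip)] <- 0
  fixed[match(names(ages), tree$node.label) + n_tip] <- ages
  age <- fixed
  for (v in (n_tip + 1L):n_all) {
    if (!is.na(fixed[v])) next
    ## walk up
    a <- par[v]; ka <- 1L
    while (is.na(fixed[a])) { a <- par[a]; ka <- ka + 1L }
    ## BFS down, not expanding past constrained nodes
    frontier <- kids[[v]]; kd <- 1L
    found_age <- NULL
    while (is.null(found_age) && length(frontier)) {
      hit <- frontier[!is.na(fixed[frontier])]
      if (length(hit)) {
        found_age <- max(fixed[hit])
      } else {
        frontier <- unlist(kids[frontier])
        kd <- kd + 1L
      }
    }
    m <- ka + kd
    age[v] <- fixed[a] - (fixed[a] - found_age) * ka / m
  }
  for (v in lianevol:::preorder_all(tree))
    if (v != n_tip + 1L && age[v] > age[par[v]]) age[v] <- age[par[v]]
  age
}

## Brownian likelihood by Felsenstein pruning (contrasts route), fully
## independent of the GLS-matrix route in bm_loglik().
oracle_bm_loglik_pruning <- function(tree, y, sigma2, mu) {
  n_tip <- length(tree$tip.label)
  elen <- numeric(n_tip + tree$Nnode)
  elen[tree$edge[, 2]] <- tree$edge.length
  kids <- lianevol:::children_list(tree)
  yv <- as.numeric(y[tree$tip.label])
  rec <- function(v) {
    if (v <= n_tip)
      return(list(x = yv[v], v = elen[v], ll = 0))
    parts <- lapply(kids[[v]], rec)
    while (length(parts) > 1) {
      a <- parts[[1]]; b <- parts[[2]]
      ll <- a$ll + b$ll +
        stats::dnorm(a$x - b$x, 0, sqrt(sigma2 * (a$v + b$v)),
                     log = TRUE)
      xm <- (a$x / a$v + b$x / b$v) / (1 / a$v + 1 / b$v)
      parts <- c(list(list(x = xm, v = a$v * b$v / (a$v + b$v),
                           ll = ll)),
                 parts[-(1:2)])
    }
    r <- parts[[1]]
    list(x = r$x, v = r$v + elen[v], ll = r$ll)
  }
  root <- rec(n_tip + 1L)
  root$ll + stats::dnorm(root$x, mu, sqrt(sigma2 * root$v), log = TRUE)
}

## Mk likelihood by brute-force enumeration of internal-state
## assignments (2^Nnode terms).
oracle_mk_brute <- function(tree, tip_states, q12, q21, prior,
                            states = c("liana", "tree")) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  tips <- match(tip_states[tree$tip.label], states)
  total <- 0
  for (code in 0:(2^n_int - 1)) {
    assign_int <- as.integer(intToBits(code))[seq_len(n_int)] + 1L
    st <- c(tips, assign_int)
    pr <- prior[st[n_tip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      P <- lianevol:::mk_pmat(q12, q21, tree$edge.length[e])
      pr <- pr * P[st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    }
    total <- total + pr
  }
  log(total)
}

## Endpoint-conditioned expected time in state 1 on a single branch,
## by numerical integration of the occupancy formula.
oracle_time_in_state1 <- function(s_from, s_to, t, q) {
  P <- function(i, j, s) lianevol:::mk_pmat(q, q, s)[i, j]
  dens <- function(s) vapply(s, function(u)
    P(s_from, 1L, u) * P(1L, s_to, t - u), numeric(1))
  stats::integrate(dens, 0, t)$value / P(s_from, s_to, t)
}

## Mean pairwise distance by explicit double loop.
oracle_mpd_loop <- function(D, taxa) {
  tot <- 0; np <- 0
  for (i in seq_along(taxa))
    for (j in seq_along(taxa))
      if (i < j) {
        tot <- tot + D[taxa[i], taxa[j]]
        np <- np + 1
      }
  tot / np
}
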