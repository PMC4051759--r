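#' Number of unordered species pairs
#'
#' `n (n - 1) / 2` — e.g. the pooled 134-species analysis draws its null
#' from 8911 pairs.
#'
#' @param n Species count (>= 2).
#' @return Integer pair count.
#' @export
n_pairs <- function(n) {
  if (n < 2) stop("need n >= 2", call. = FALSE)
  as.integer(round(n * (n - 1) / 2))
}

#' Mean pairwise distance of a set of taxa
#'
#' Arithmetic mean of the `n (n - 1) / 2` unordered pairwise distances
#' among `taxa` in a phylogenetic or trait distance matrix.
#'
#' @param dist Symmetric distance matrix with taxon dimnames.
#' @param taxa Character vector of taxa (>= 2, all present in `dist`).
#' @return Scalar mean pairwise distance.
#' @export
mpd <- function(dist, taxa = rownames(dist)) {
  if (length(taxa) < 2) stop("need at least 2 taxa", call. = FALSE)
  miss <- setdiff(taxa, rownames(dist))
  if (length(miss))
    stop("taxa not in distance matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  D <- dist[taxa, taxa]
  sum(D[upper.tri(D)]) / n_pairs(length(taxa))
}

#' Pairwise trait distance matrix
#'
#' Absolute pairwise differences of one trait (equivalently the Euclidean
#' distance for a single trait), optionally (default) after z-scoring
#' across the included species, which makes the matrix invariant to
#' affine rescaling of the raw measurements.  Species with missing values
#' are dropped.
#'
#' @param values Named numeric vector of one trait.
#' @param standardize Z-score before differencing (default `TRUE`).
#' @return Symmetric matrix with species dimnames, zero diagonal.
#' @export
trait_distance <- function(values, standardize = TRUE) {
  v <- values[!is.na(values)]
  if (length(v) < 2)
    stop("need at least 2 species with trait values", call. = FALSE)
  if (standardize) {
    s <- stats::sd(v)
    v <- if (s > 0) (v - mean(v)) / s else v - mean(v)
  }
  abs(outer(v, v, `-`))
}

#' Standardized effect size of mean pairwise distance
#'
#' Compares the observed MPD of a group against a null built by drawing
#' `n_reps` random groups of the same size from the pool (equivalent, for
#' MPD, to reshuffling species labels across the tree / distance matrix).
#' Returns `z = (obs - mean(null)) / sd(null)` and the rank-based
#' quantile `p = (#\{null <= obs\} + 1) / (n_reps + 1)`, so `p > 0.95`
#' indicates significant evenness (overdispersion) and `p < 0.05`
#' significant clustering.
#'
#' @param dist Phylogenetic or trait distance matrix.
#' @param group Taxa of the focal group (strict subset of `pool`).
#' @param pool Taxa defining the randomization pool (default all taxa in
#'   `dist`).
#' @param n_reps Number of null randomizations (>= 99; default 999).
#' @param seed Integer seed.
#' @param group_label Optional label stored in the result.
#' @return Object of class `ses_result`: `group`, `n_taxa`, `obs`,
#'   `null_mean`, `null_sd`, `z`, `p`, `n_reps`, `seed`, `degenerate`.
#' @export
ses <- function(dist, group, pool = rownames(dist), n_reps = 999,
                seed = 1L, group_label = NULL) {
  stopifnot(n_reps >= 99)
  if (!all(group %in% pool))
    stop("group must be a subset of the pool", call. = FALSE)
  if (length(group) >= length(pool))
    stop("group must be a strict subset of the pool ",
         "(the null is degenerate otherwise)", call. = FALSE)
  if (length(group) < 2) stop("need a group of >= 2 taxa", call. = FALSE)
  Dp <- dist[pool, pool]
  k <- length(group)
  obs <- mpd(dist, group)
  null <- with_local_seed(seed, {
    Z <- matrix(0, length(pool), n_reps)
    for (r in seq_len(n_reps))
      Z[sample.int(length(pool), k), r] <- 1
    colSums(Z * (Dp %*% Z)) / (k * (k - 1))
  })
  mu <- mean(null); sdv <- stats::sd(null)
  degenerate <- sdv == 0
  structure(list(group = if (is.null(group_label)) NA_character_
                 else group_label,
                 n_taxa = k, obs = obs, null_mean = mu, null_sd = sdv,
                 z = if (degenerate) NA_real_ else (obs - mu) / sdv,
                 p = (sum(null <= obs) + 1) / (n_reps + 1),
                 n_reps = n_reps, seed = seed, degenerate = degenerate),
            class = "ses_result")
}
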