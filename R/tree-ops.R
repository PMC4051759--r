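#' Resolve polytomies at random, reproducibly
#'
#' Thin seeded wrapper around [ape::multi2di()] (`random = TRUE`): every
#' multifurcation is expanded into a random sequence of bifurcations joined
#' by zero-length branches, so root-to-tip path lengths — and hence all
#' cophenetic distances that do not pass through an inserted branch — are
#' unchanged.  The global RNG state is left untouched.
#'
#' @param tree A \code{phylo}.
#' @param seed Integer seed controlling which resolution is drawn.
#' @return A strictly bifurcating \code{phylo}; newly created internal
#'   nodes are auto-named.
#' @export
resolve_polytomies <- function(tree, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (ape::is.binary(tree)) return(tree)
  out <- with_local_seed(seed, ape::multi2di(tree, random = TRUE))
  autoname_nodes(out)
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Prune a tree to a set of taxa
#'
#' Returns the induced subtree on `taxa`: other tips are dropped and
#' degree-2 internal nodes are suppressed with their branch lengths summed,
#' so pairwise path distances among the retained taxa are preserved.
#'
#' @param tree A \code{phylo}.
#' @param taxa Character vector of tip labels to keep (at least 1).
#' @return The pruned \code{phylo}.
#' @export
prune_to <- function(tree, taxa) {
  stopifnot(inherits(tree, "phylo"), length(taxa) >= 1)
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing))
    stop("taxa not in tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(taxa) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}

#' Cophenetic (patristic) distance matrix
#'
#' Entry (i, j) is the sum of branch lengths on the path between tips i
#' and j, in Myr for a calibrated tree.  Computed directly on the tree —
#' no clustering step is involved.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @return Symmetric matrix with tip labels as dimnames, zero diagonal.
#' @export
cophenetic_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  as.matrix(ape::cophenetic.phylo(tree))
}

#' Phylogenetic variance-covariance matrix
#'
#' Under Brownian motion the covariance of trait values at two tips is
#' proportional to their shared history: C[i, j] is the root-to-MRCA path
#' length, C[i, i] the tip's depth.  On an ultrametric tree
#' `d(i,j) = C[i,i] + C[j,j] - 2 C[i,j]` relates this to
#' [cophenetic_matrix()].
#'
#' @param tree A rooted \code{phylo} with branch lengths.
#' @return Symmetric positive-semidefinite matrix (tip labels as dimnames).
#' @export
vcv_matrix <- function(tree) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  ape::vcv(tree)
}
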