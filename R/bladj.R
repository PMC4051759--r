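#' Read a node-age constraint table
#'
#' Two-column CSV (`node_label`, `age_myr`) mapping internal-node labels to
#' fixed ages in millions of years before present.
#'
#' @param path Path to the CSV file.
#' @return Named numeric vector of ages (names are node labels).
#' @export
read_age_constraints <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 2)
    stop("age constraint table needs columns (node_label, age_myr)",
         call. = FALSE)
  ages <- as.numeric(tab[[2]])
  names(ages) <- as.character(tab[[1]])
  validate_age_constraints(ages)
  ages
}

validate_age_constraints <- function(ages) {
  if (anyNA(ages)) stop("missing ages in constraint table", call. = FALSE)
  if (any(ages < 0)) stop("constraint ages must be >= 0", call. = FALSE)
  if (anyDuplicated(names(ages)))
    stop("duplicate node labels in constraint table", call. = FALSE)
  invisible(ages)
}

#' Calibrate node ages by even interpolation (BLADJ-style smoothing)
#'
#' Fixes a subset of internal nodes to specified ages and distributes the
#' ages of the remaining nodes evenly between them, the branch-length
#' adjustment originally implemented in Phylocom's `bladj`.  Every
#' unconstrained internal node receives the age obtained by linear
#' interpolation between its nearest constrained ancestor and its nearest
#' constrained descendant, where "nearest" counts nodes along the path and
#' tips act as age-0 constraints.  When several constrained descendants tie
#' for topological distance the oldest is used, which keeps ancestors at
#' least as old as the interpolation through any other tied path.  Nodes
#' are processed in preorder and, as a final guard, every age is clamped to
#' its parent's age so branch lengths cannot be negative.
#'
#' Interpolated ages never act as constraints for other nodes, so the
#' operation is idempotent: re-smoothing with the same constraint set
#' reproduces the same ages.
#'
#' @param tree A \code{phylo}; branch lengths are ignored and recomputed.
#'   Internal nodes must be labeled (see [read_newick()] auto-naming).
#' @param ages Named numeric vector: internal-node label -> age (Myr).  The
#'   root must be constrained.  Tips are taken as extant (age 0).
#' @return A calibrated ultrametric \code{phylo} whose branch lengths are
#'   differences of the assigned ages.
#' @export
bladj_smooth <- function(tree, ages) {
  stopifnot(inherits(tree, "phylo"))
  validate_age_constraints(ages)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label)))
    tree <- autoname_nodes(tree)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  root <- n_tip + 1L

  unknown <- setdiff(names(ages), tree$node.label)
  if (length(unknown))
    stop("constraint labels not found among internal nodes: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  constrained_age <- rep(NA_real_, n_all)
  constrained_age[match(names(ages), tree$node.label) + n_tip] <- ages
  constrained_age[seq_len(n_tip)] <- 0    # extant tips
  if (is.na(constrained_age[root]))
    stop("the root must have a fixed age", call. = FALSE)

  parent <- parent_vec(tree)
  children <- children_list(tree)
  pre <- preorder_all(tree)

  ## consistency: a constrained descendant never older than a constrained
  ## ancestor (checked on the nearest constrained ancestor of each
  ## constrained node)
  for (v in pre) {
    if (v == root || is.na(constrained_age[v])) next
    a <- parent[v]
    while (is.na(constrained_age[a])) a <- parent[a]
    if (constrained_age[v] > constrained_age[a] + 1e-12)
      stop("inconsistent constraints: node '", node_label_of(tree, v),
           "' (", constrained_age[v], " Myr) older than its constrained ",
           "ancestor '", node_label_of(tree, a), "' (",
           constrained_age[a], " Myr)", call. = FALSE)
  }

  ## nearest constrained descendant: distance in edges and (max) age,
  ## computed bottom-up
  dn_dist <- rep(NA_integer_, n_all)
  dn_age <- rep(NA_real_, n_all)
  for (v in rev(pre)) {
    if (!is.na(constrained_age[v])) {
      dn_dist[v] <- 0L
      dn_age[v] <- constrained_age[v]
    } else {
      kd <- dn_dist[children[[v]]] + 1L
      ka <- dn_age[children[[v]]]
      m <- min(kd)
      dn_dist[v] <- m
      dn_age[v] <- max(ka[kd == m])   # tie -> oldest
    }
  }

  ## preorder assignment: interpolate between nearest constrained ancestor
  ## (tracked while descending) and nearest constrained descendant
  age <- constrained_age
  up_dist <- integer(n_all)   # edges to nearest constrained ancestor
  for (v in pre) {
    if (v == root) next
    p <- parent[v]
    up_dist[v] <- if (is.na(constrained_age[p])) up_dist[p] + 1L else 1L
    if (is.na(age[v])) {
      anc <- p
      while (is.na(constrained_age[anc])) anc <- parent[anc]
      k <- up_dist[v]
      m <- k + dn_dist[v]
      age[v] <- constrained_age[anc] -
        (constrained_age[anc] - dn_age[v]) * k / m
    }
    if (age[v] > age[p]) age[v] <- age[p]   # guard, see details
  }

  tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
  tree
}

node_label_of <- function(tree, v) {
  n_tip <- length(tree$tip.label)
  if (v <= n_tip) tree$tip.label[v] else tree$node.label[v - n_tip]
}
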