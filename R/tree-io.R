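#' Read a Newick tree as a calibrated phylogeny
#'
#' Parses a Newick string into an `ape` \code{phylo} object and validates it
#' for downstream comparative analyses: tip labels must be unique, every
#' branch needs a non-negative length, and unlabeled internal nodes are
#' auto-named \code{nd<k>} by preorder (cladewise) index so that age
#' constraints can address them.
#'
#' @param text Newick string (single tree, terminated by `;`).
#' @param require_lengths If `TRUE` (default) every edge must carry a branch
#'   length; set `FALSE` for topology-only backbones destined for
#'   [bladj_smooth()].
#' @return A \code{phylo} object with complete `node.label`.
#' @seealso [write_newick()], [bladj_smooth()]
#' @export
read_newick <- function(text, require_lengths = TRUE) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_parens(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse error: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop("Newick parse error: no tree found in input", call. = FALSE)
  validate_tree(tree, require_lengths = require_lengths)
  autoname_nodes(tree)
}

## Report the position of the first unbalanced parenthesis (ape's parser
## gives no location info).
check_newick_parens <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at position ", i,
             call. = FALSE)
    }
  }
  if (depth != 0L)
    stop("Newick parse error: ", depth,
         " unclosed '(' at end of string", call. = FALSE)
  invisible(TRUE)
}

validate_tree <- function(tree, require_lengths = TRUE) {
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "), call. = FALSE)
  if (require_lengths) {
    if (is.null(tree$edge.length))
      stop("tree has no branch lengths", call. = FALSE)
    if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
      stop("branch lengths must be non-negative and non-missing",
           call. = FALSE)
  }
  invisible(tree)
}

## Assign labels "nd<preorder index>" to unlabeled internal nodes.  The
## preorder index is the rank of the node in a cladewise edge traversal
## (root = 1), so naming is deterministic for a given topology.
autoname_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", n_node)
  labs[is.na(labs)] <- ""
  ord <- preorder_nodes(tree)           # internal node numbers, root first
  pre_rank <- integer(n_node)
  pre_rank[ord - n_tip] <- seq_along(ord)
  empty <- !nzchar(labs)
  labs[empty] <- paste0("nd", pre_rank[empty])
  if (anyDuplicated(labs))
    stop("duplicate internal node labels after auto-naming: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "),
         call. = FALSE)
  tree$node.label <- labs
  tree
}

## Internal node numbers in preorder (parents before children).
preorder_nodes <- function(tree) {
  edge <- reorder(tree, "cladewise")$edge
  n_tip <- length(tree$tip.label)
  seen <- unique(c(n_tip + 1L, edge[edge[, 2] > n_tip, 2]))
  seen
}

## All node numbers (tips and internals) in preorder.
preorder_all <- function(tree) {
  edge <- reorder(tree, "cladewise")$edge
  n_tip <- length(tree$tip.label)
  unique(c(n_tip + 1L, edge[, 2]))
}

#' Write a tree to Newick with deterministic child order
#'
#' Serializes a phylogeny to Newick at full double precision.  Children of
#' every node are ordered lexicographically by the smallest tip label they
#' subtend, so the output string is a canonical form: two trees with the
#' same topology, labels and lengths serialize identically.
#'
#' @param tree A \code{phylo} object.
#' @param digits Significant digits for branch lengths (default 15).
#' @return A single Newick string.
#' @export
write_newick <- function(tree, digits = 15) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- children_list(tree)
  edge_len <- numeric(n_tip + tree$Nnode)
  edge_len[tree$edge[, 2]] <- if (is.null(tree$edge.length))
    NA_real_ else tree$edge.length
  node_lab <- function(v) {
    if (v <= n_tip) tree$tip.label[v]
    else if (!is.null(tree$node.label)) tree$node.label[v - n_tip]
    else ""
  }
  ## smallest tip label under each node, for canonical child order
  min_tip <- character(n_tip + tree$Nnode)
  po <- rev(preorder_all(tree))
  for (v in po) {
    min_tip[v] <- if (v <= n_tip) tree$tip.label[v]
    else min(min_tip[children[[v]]])
  }
  fmt_len <- function(v) {
    if (is.na(edge_len[v])) "" else
      paste0(":", format(edge_len[v], digits = digits, scientific = FALSE))
  }
  rec <- function(v) {
    if (v <= n_tip) return(paste0(node_lab(v), fmt_len(v)))
    kids <- children[[v]]
    kids <- kids[order(min_tip[kids])]
    inner <- paste(vapply(kids, rec, character(1)), collapse = ",")
    paste0("(", inner, ")", node_lab(v), if (v != root) fmt_len(v) else "")
  }
  paste0(rec(root), ";")
}

## children_list[[v]] = child node numbers of v (empty for tips)
children_list <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  out <- vector("list", n)
  for (i in seq_len(nrow(tree$edge)))
    out[[tree$edge[i, 1]]] <- c(out[[tree$edge[i, 1]]], tree$edge[i, 2])
  out
}

## parent[v] = parent node number (0 for root)
parent_vec <- function(tree) {
  n <- length(tree$tip.label) + tree$Nnode
  p <- integer(n)
  p[tree$edge[, 2]] <- tree$edge[, 1]
  p
}

#' Node depths and ages
#'
#' `node_depths()` returns each node's distance from the root along the
#' tree; `node_ages()` returns ages in Myr before present (max tip depth
#' minus depth), so extant tips of an ultrametric tree have age 0.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @return Numeric vector indexed by node number (tips first, as in
#'   \code{phylo} numbering).
#' @export
node_depths <- function(tree) {
  stopifnot(!is.null(tree$edge.length))
  n <- length(tree$tip.label) + tree$Nnode
  d <- numeric(n)
  ord <- reorder(tree, "cladewise")
  len <- ord$edge.length
  for (i in seq_len(nrow(ord$edge)))
    d[ord$edge[i, 2]] <- d[ord$edge[i, 1]] + len[i]
  d
}

#' @rdname node_depths
#' @export
node_ages <- function(tree) {
  d <- node_depths(tree)
  max(d[seq_along(tree$tip.label)]) - d
}

#' Test ultrametricity of a calibrated tree
#'
#' All tip depths must agree to a relative tolerance (default `1e-6`),
#' the criterion used throughout the package for declaring a tree
#' time-calibrated with contemporaneous tips.
#'
#' @param tree A \code{phylo} with branch lengths.
#' @param tol Relative tolerance on tip depths.
#' @return Logical scalar.
#' @export
is_calibrated_ultrametric <- function(tree, tol = 1e-6) {
  d <- node_depths(tree)[seq_along(tree$tip.label)]
  dm <- max(d)
  if (dm == 0) return(TRUE)
  (dm - min(d)) / dm <= tol
}
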