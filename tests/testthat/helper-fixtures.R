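## Shared fixtures: tiny trees built in code.

toy_tree <- function() read_newick("((A:1,B:1):1,C:2);")

## root(R) -> X -> Y -> single tip, all branches 1 (built by hand: ape's
## parser misorders labels on singleton chains)
chain_tree <- function() {
  structure(list(edge = matrix(c(2L, 3L, 3L, 4L, 4L, 1L), 3, 2,
                               byrow = TRUE),
                 Nnode = 3L, tip.label = "t",
                 node.label = c("R", "X", "Y"),
                 edge.length = c(1, 1, 1)),
            class = "phylo", order = "cladewise")
}

star_tree <- function(n, depth = 1) {
  tree <- structure(list(edge = cbind(rep(n + 1L, n), seq_len(n)),
                         Nnode = 1L,
                         tip.label = sprintf("s%02d", seq_len(n)),
                         edge.length = rep(depth, n)),
                    class = "phylo", order = "cladewise")
  lianevol:::autoname_nodes(tree)
}

random_tree <- function(n, seed, root_age = 100)
  simulate_tree(n, root_age = root_age, seed = seed)

## greedy subset maximizing total pairwise distance (evenness fixture)
greedy_even_subset <- function(D, k) {
  start <- which(D == max(D), arr.ind = TRUE)[1, ]
  sel <- rownames(D)[start]
  while (length(sel) < k) {
    rest <- setdiff(rownames(D), sel)
    gain <- colSums(D[sel, rest, drop = FALSE])
    sel <- c(sel, rest[which.max(gain)])
  }
  sel
}

## run expr under a seed, swallowing package chatter (phytools prints)
with_seed_quiet <- function(seed, expr) {
  set.seed(seed)
  res <- NULL
  utils::capture.output(res <- suppressMessages(expr))
  res
}

quiet_brownie <- function(pm, y) {
  res <- NULL
  utils::capture.output(res <- phytools::brownie.lite(pm, y))
  res
}

## Brownian simulation on a single-rate tree (no state dependence)
sim_bm <- function(tree, sigma2, seed, root_value = 0) {
  hist1 <- lapply(seq_len(nrow(tree$edge)), function(e)
    stats::setNames(tree$edge.length[e], "s"))
  simulate_bm_multirate(tree, hist1, c(s = sigma2), root_value,
                        seed = seed)
}
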