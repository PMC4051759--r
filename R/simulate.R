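#' Configuration for the synthetic liana/tree dataset generator
#'
#' Bundles every parameter of the generator into one validated list.  The
#' defaults emulate the scale of the pooled field dataset the pipeline is
#' designed for: 63 liana and 71 tree species on an angiosperm-scale
#' ultrametric tree (root age 150 Myr), a phylogenetically structured
#' binary growth-form character evolved under a symmetric Mk model, three
#' continuous traits (Amax, Rd, SLA) evolving by state-dependent Brownian
#' motion at rates of order 0.1 per Myr on a standardized scale, and
#' per-trait/per-group missingness tuned so available sample sizes span
#' 26 (Rd in lianas) to 67 (Amax in trees).
#'
#' @param n_liana,n_tree Number of liana and tree species.
#' @param root_age Root age in Myr.
#' @param birth_rate Pure-birth speciation rate (per Myr, before
#'   rescaling to `root_age`).
#' @param q Mk transition rate between growth forms (per Myr,
#'   off-diagonal of the symmetric rate matrix).
#' @param sigma2 Named list, one element per trait, each a named numeric
#'   vector of Brownian rates per state (`liana`, `tree`),
#'   trait-variance units per Myr.
#' @param root_value Trait value at the root (standardized scale).
#' @param missingness Named list per trait, each a named numeric vector of
#'   missingness fractions per group in `[0, 1)`.  The number of masked
#'   cells is `round(fraction * group size)`, so available counts are
#'   deterministic; which cells are masked depends on the seed.
#' @param growth_form_mode `"mk"` (default): growth form evolves under the
#'   Mk model, redrawn until one state has exactly `n_liana` tips;
#'   `"clade"`: the clade whose size is closest to `n_liana` is painted
#'   liana, a fixture with maximal phylogenetic clustering.
#' @param sites Character vector of site names sampled uniformly per
#'   species.
#' @param seed Integer seed; every draw the generator makes derives
#'   from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_liana = 63L,
                       n_tree = 71L,
                       root_age = 150,
                       birth_rate = 1,
                       q = 0.01,
                       sigma2 = list(
                         Amax = c(liana = 0.075, tree = 0.075),
                         Rd   = c(liana = 0.148, tree = 0.083),
                         SLA  = c(liana = 0.093, tree = 0.103)),
                       root_value = 0,
                       missingness = list(
                         Amax = c(liana = 8 / 63,  tree = 4 / 71),
                         Rd   = c(liana = 37 / 63, tree = 31 / 71),
                         SLA  = c(liana = 18 / 63, tree = 16 / 71)),
                       growth_form_mode = c("mk", "clade"),
                       sites = c("Gamboa", "San Lorenzo", "Riberalta",
                                 "Xishuangbanna", "Yakushidake",
                                 "Beltsville", "Puyehue"),
                       seed = 42L) {
  growth_form_mode <- match.arg(growth_form_mode)
  stopifnot(n_liana >= 1, n_tree >= 1, root_age > 0, birth_rate > 0,
            q > 0, root_value >= -Inf, length(seed) == 1)
  for (tr in names(sigma2))
    if (any(sigma2[[tr]] <= 0))
      stop("all Brownian rates must be > 0", call. = FALSE)
  for (tr in names(missingness))
    if (any(missingness[[tr]] < 0 | missingness[[tr]] >= 1))
      stop("missingness fractions must be in [0, 1)", call. = FALSE)
  structure(list(n_liana = as.integer(n_liana),
                 n_tree = as.integer(n_tree),
                 n_tips = as.integer(n_liana + n_tree),
                 root_age = root_age, birth_rate = birth_rate, q = q,
                 sigma2 = sigma2, root_value = root_value,
                 missingness = missingness,
                 growth_form_mode = growth_form_mode,
                 sites = sites, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a pure-birth ultrametric tree
#'
#' Forward Yule simulation: starting from two lineages at the root, each
#' of k extant lineages splits at total rate `k * birth_rate`; the process
#' stops when `n_tips` lineages exist and the present is set one further
#' exponential waiting time later.  By default the tree is rescaled so the
#' root age equals `root_age`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param root_age Target root age, Myr (ignored if `rescale = FALSE`).
#' @param birth_rate Speciation rate per lineage.
#' @param seed Integer seed.
#' @param rescale Rescale depth to `root_age`? Set `FALSE` to keep the raw
#'   simulation timescale (e.g. to check lineage-through-time behaviour).
#' @return An ultrametric \code{phylo} with tips `sp001`, `sp002`, ...
#' @export
simulate_tree <- function(n_tips, root_age = 150, birth_rate = 1,
                          seed = 1L, rescale = TRUE) {
  stopifnot(n_tips >= 2)
  n_tips <- as.integer(n_tips)
  with_local_seed(seed, {
    ## active lineages: parent internal node and birth time of the lineage
    par_node <- c(n_tips + 1L, n_tips + 1L)
    born <- c(0, 0)
    next_node <- n_tips + 2L
    t_now <- 0
    edges <- matrix(0L, 2L * n_tips - 2L, 2L)
    elen <- numeric(2L * n_tips - 2L)
    n_edge <- 0L
    while (length(par_node) < n_tips) {
      k <- length(par_node)
      t_now <- t_now + stats::rexp(1, k * birth_rate)
      i <- sample.int(k, 1L)
      w <- next_node; next_node <- next_node + 1L
      n_edge <- n_edge + 1L
      edges[n_edge, ] <- c(par_node[i], w)
      elen[n_edge] <- t_now - born[i]
      par_node <- c(par_node[-i], w, w)
      born <- c(born[-i], t_now, t_now)
    }
    t_present <- t_now + stats::rexp(1, n_tips * birth_rate)
    for (i in seq_along(par_node)) {
      n_edge <- n_edge + 1L
      edges[n_edge, ] <- c(par_node[i], i)
      elen[n_edge] <- t_present - born[i]
    }
    tree <- structure(list(edge = edges, edge.length = elen,
                           tip.label = sprintf("sp%03d", seq_len(n_tips)),
                           Nnode = n_tips - 1L),
                      class = "phylo")
    tree <- reorder(tree, "cladewise")
    if (rescale) tree$edge.length <- tree$edge.length * root_age / t_present
    autoname_nodes(tree)
  })
}

#' Simulate a binary character under a symmetric Mk model
#'
#' Evolves a 2-state continuous-time Markov character (transition rate `q`
#' in each direction) forward along every branch from a root state drawn
#' uniformly, recording the exact timed state history of every branch.
#'
#' @param tree A calibrated \code{phylo}.
#' @param q Transition rate per Myr (> 0).
#' @param seed Integer seed.
#' @param states Character vector of the two state labels.
#' @param root_state Optional fixed root state (otherwise drawn uniformly).
#' @return List with `tip_states` (named character), `node_states`
#'   (states at all nodes, indexed by node number), and `history`: one
#'   element per edge (in `tree$edge` row order), a numeric vector of
#'   segment durations named by state, ordered rootward to tipward.
#' @export
simulate_discrete <- function(tree, q, seed = 1L,
                              states = c("liana", "tree"),
                              root_state = NULL) {
  stopifnot(inherits(tree, "phylo"), q > 0, length(states) == 2)
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  ord <- order_edges_preorder(tree)
  with_local_seed(seed, {
    node_state <- character(n_all)
    node_state[n_tip + 1L] <- if (is.null(root_state))
      sample(states, 1L) else match.arg(root_state, states)
    history <- vector("list", nrow(tree$edge))
    for (e in ord) {
      cur <- node_state[tree$edge[e, 1]]
      rem <- tree$edge.length[e]
      durs <- numeric(0); labs <- character(0)
      repeat {
        w <- stats::rexp(1, q)
        if (w >= rem) {
          durs <- c(durs, rem); labs <- c(labs, cur)
          break
        }
        durs <- c(durs, w); labs <- c(labs, cur)
        rem <- rem - w
        cur <- states[states != cur]
      }
      history[[e]] <- stats::setNames(durs, labs)
      node_state[tree$edge[e, 2]] <- cur
    }
    tips <- stats::setNames(node_state[seq_len(n_tip)], tree$tip.label)
    list(tip_states = tips, node_states = node_state, history = history)
  })
}

## edge row indices in preorder (parent visited before child edges)
order_edges_preorder <- function(tree) {
  ord <- reorder(tree, "cladewise")
  match(paste(ord$edge[, 1], ord$edge[, 2]),
        paste(tree$edge[, 1], tree$edge[, 2]))
}

#' Simulate a trait under state-dependent Brownian motion
#'
#' Given an exact timed state history (from [simulate_discrete()] or a
#' stochastic map), accumulates independent Gaussian increments per
#' segment with variance `sigma2[state] * duration`, summed from root to
#' tip.
#'
#' @param tree A calibrated \code{phylo}.
#' @param history Per-edge segment history as produced by
#'   [simulate_discrete()].
#' @param sigma2 Named numeric vector of Brownian rate per state (>= 0).
#' @param root_value Trait value at the root.
#' @param seed Integer seed.
#' @return Named numeric vector of tip trait values.
#' @export
simulate_bm_multirate <- function(tree, history, sigma2, root_value = 0,
                                  seed = 1L) {
  stopifnot(inherits(tree, "phylo"), length(history) == nrow(tree$edge))
  used <- unique(unlist(lapply(history, names)))
  miss <- setdiff(used, names(sigma2))
  if (length(miss))
    stop("no Brownian rate supplied for state(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(sigma2 < 0)) stop("sigma2 must be >= 0", call. = FALSE)
  n_tip <- length(tree$tip.label)
  ord <- order_edges_preorder(tree)
  with_local_seed(seed, {
    val <- numeric(n_tip + tree$Nnode)
    val[n_tip + 1L] <- root_value
    for (e in ord) {
      segs <- history[[e]]
      v <- sigma2[names(segs)] * segs
      inc <- if (length(v)) sum(stats::rnorm(length(v), 0, sqrt(v))) else 0
      val[tree$edge[e, 2]] <- val[tree$edge[e, 1]] + inc
    }
    stats::setNames(val[seq_len(n_tip)], tree$tip.label)
  })
}

#' Generate a complete synthetic liana/tree dataset
#'
#' Runs the full generator: pure-birth tree, growth-form character with
#' exact group sizes, state-dependent Brownian traits, site labels, and
#' seeded per-trait/per-group missingness.  Optionally writes the dataset
#' to disk (`tree.nwk`, `traits.csv`, `config.yml`).
#'
#' In `"mk"` mode the growth-form character is redrawn (with fresh
#' sub-seeds) until one state is carried by exactly `n_liana` tips; that
#' state is labeled `liana`.  In `"clade"` mode the clade closest in size
#' to `n_liana` is painted liana and the stem branch of that clade changes
#' state at its midpoint.
#'
#' @param config A [sim_config()] object.
#' @param dir Optional output directory (created if needed).
#' @return A list of class `sim_dataset`: `tree`, `tip_states`,
#'   `node_states`, `history` (true per-branch state segments),
#'   `traits` (data frame: species, growth_form, site, one column per
#'   trait, `NA` = missing), and `config`.
#' @export
make_dataset <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  tree <- simulate_tree(config$n_tips, config$root_age, config$birth_rate,
                        seed = config$seed)
  gf <- draw_growth_form(tree, config)
  traits <- list()
  tr_names <- names(config$sigma2)
  for (i in seq_along(tr_names)) {
    tr <- tr_names[i]
    traits[[tr]] <- simulate_bm_multirate(
      tree, gf$history, config$sigma2[[tr]], config$root_value,
      seed = config$seed + 1000L + i)
  }
  tab <- data.frame(species = tree$tip.label,
                    growth_form = unname(gf$tip_states[tree$tip.label]),
                    site = with_local_seed(
                      config$seed + 7L,
                      sample(config$sites, config$n_tips, replace = TRUE)),
                    stringsAsFactors = FALSE)
  for (tr in tr_names) tab[[tr]] <- unname(traits[[tr]][tab$species])
  ## seeded masking with deterministic per-cell counts
  for (i in seq_along(tr_names)) {
    tr <- tr_names[i]
    mfrac <- config$missingness[[tr]]
    if (is.null(mfrac)) next
    for (g in names(mfrac)) {
      rows <- which(tab$growth_form == g)
      n_miss <- round(mfrac[[g]] * length(rows))
      if (n_miss > 0) {
        drop <- with_local_seed(config$seed + 2000L + 10L * i +
                                  match(g, names(mfrac)),
                                sample(rows, n_miss))
        tab[[tr]][drop] <- NA_real_
      }
    }
  }
  ds <- structure(list(tree = tree, tip_states = gf$tip_states,
                       node_states = gf$node_states, history = gf$history,
                       traits = tab, config = config),
                  class = "sim_dataset")
  if (!is.null(dir)) write_dataset(ds, dir)
  ds
}

draw_growth_form <- function(tree, config) {
  if (config$growth_form_mode == "clade")
    return(paint_clade_liana(tree, config$n_liana))
  max_try <- 5000L
  for (k in seq_len(max_try)) {
    sim <- simulate_discrete(tree, config$q, seed = config$seed + k)
    counts <- table(factor(sim$tip_states, levels = c("liana", "tree")))
    if (counts[["liana"]] == config$n_liana) return(sim)
    if (counts[["tree"]] == config$n_liana) {  # swap the labels
      flip <- c(liana = "tree", tree = "liana")
      sim$tip_states[] <- flip[sim$tip_states]
      sim$node_states <- unname(flip[sim$node_states])
      sim$history <- lapply(sim$history, function(s)
        stats::setNames(s, flip[names(s)]))
      return(sim)
    }
  }
  stop("could not draw a growth-form character with exactly ",
       config$n_liana, " lianas in ", max_try,
       " attempts; adjust q or group sizes", call. = FALSE)
}

## "clade" mode: strong phylogenetic clustering fixture
paint_clade_liana <- function(tree, n_liana) {
  n_tip <- length(tree$tip.label)
  sizes <- vapply((n_tip + 2L):(n_tip + tree$Nnode), function(v)
    length(tips_under(tree, v)), integer(1))
  best <- which.min(abs(sizes - n_liana)) + n_tip + 1L
  liana_tips <- tips_under(tree, best)
  tip_states <- stats::setNames(rep("tree", n_tip), tree$tip.label)
  tip_states[tree$tip.label[liana_tips]] <- "liana"
  inside <- c(liana_tips, best, internal_under(tree, best))
  node_states <- rep("tree", n_tip + tree$Nnode)
  node_states[inside] <- "liana"
  node_states[best] <- "liana"
  history <- vector("list", nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    if (child == best) {
      history[[e]] <- stats::setNames(c(len / 2, len / 2),
                                      c("tree", "liana"))
    } else if (node_states[child] == "liana") {
      history[[e]] <- stats::setNames(len, "liana")
    } else {
      history[[e]] <- stats::setNames(len, "tree")
    }
  }
  list(tip_states = tip_states, node_states = node_states,
       history = history)
}

tips_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  kids <- children_list(tree)
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n_tip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  sort(out)
}

internal_under <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  kids <- children_list(tree)
  out <- integer(0)
  stack <- kids[[node]]
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v > n_tip) { out <- c(out, v); stack <- c(stack, kids[[v]]) }
  }
  out
}

#' Write / read a synthetic dataset
#'
#' `write_dataset()` serializes a [make_dataset()] result to
#' `tree.nwk` (Newick), `traits.csv` (UTF-8, header, empty string =
#' missing) and `config.yml`.  `read_dataset()` reads the files back;
#' the true state history is in-memory only and is not round-tripped.
#'
#' @param ds A `sim_dataset`.
#' @param dir Directory to write to / read from.
#' @return `write_dataset()` the directory, invisibly; `read_dataset()` a
#'   list with `tree`, `traits`, and `config` (if present).
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(write_newick(ds$tree), file.path(dir, "tree.nwk"))
  utils::write.csv(ds$traits, file.path(dir, "traits.csv"),
                   row.names = FALSE, na = "")
  cfg <- unclass(ds$config)
  cfg$sigma2 <- lapply(cfg$sigma2, as.list)
  cfg$missingness <- lapply(cfg$missingness, as.list)
  yaml::write_yaml(cfg, file.path(dir, "config.yml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  tree <- read_newick(paste(readLines(file.path(dir, "tree.nwk")),
                            collapse = ""))
  traits <- read_trait_table(file.path(dir, "traits.csv"))
  cfg_path <- file.path(dir, "config.yml")
  config <- if (file.exists(cfg_path)) yaml::read_yaml(cfg_path) else NULL
  list(tree = tree, traits = traits, config = config)
}

#' Read a species trait table
#'
#' CSV with columns `species`, `growth_form`, `site`, and one column per
#' trait; empty cells are missing values.
#'
#' @param path CSV path.
#' @return Data frame with traits as numeric columns.
#' @export
read_trait_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  need <- c("species", "growth_form")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("trait table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  tab
}
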