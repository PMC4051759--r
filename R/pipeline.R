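#' Validate a tree / trait-table pair
#'
#' Pure report: species present in the tree but not the table (and vice
#' versa), growth-form values outside \{liana, tree\}, and the per-trait,
#' per-group available sample sizes after missing values are dropped.
#'
#' @param tree A \code{phylo}.
#' @param traits Trait data frame (see [read_trait_table()]).
#' @param trait_cols Trait column names (default: all numeric columns).
#' @return List: `only_in_tree`, `only_in_table`, `bad_growth_form`,
#'   `n_by_trait_group` (data frame trait x group with n), `n_range`.
#' @export
validate_inputs <- function(tree, traits, trait_cols = NULL) {
  if (is.null(trait_cols))
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  only_tree <- setdiff(tree$tip.label, traits$species)
  only_tab <- setdiff(traits$species, tree$tip.label)
  bad_gf <- unique(traits$growth_form[
    !traits$growth_form %in% c("liana", "tree")])
  rows <- list()
  for (tr in trait_cols)
    for (g in c("liana", "tree")) {
      n <- sum(!is.na(traits[[tr]][traits$growth_form == g]))
      rows[[length(rows) + 1L]] <- data.frame(trait = tr, group = g,
                                              n = n)
    }
  tab <- do.call(rbind, rows)
  list(only_in_tree = only_tree, only_in_table = only_tab,
       bad_growth_form = bad_gf, n_by_trait_group = tab,
       n_range = range(tab$n))
}

#' Run the full liana/tree comparative analysis
#'
#' End-to-end orchestration over a calibrated tree and species trait
#' table (or a synthetic dataset generated on the fly): polytomy
#' resolution, per-trait pruning, Mk fit and stochastic character maps of
#' growth form, single- and state-dependent Brownian rate fits with
#' profile CIs and likelihood ratio tests (rate table), standardized
#' effect sizes of mean pairwise phylogenetic and trait distance (SES
#' table), and Blomberg's K / Pagel's lambda (signal table).  Every
#' statistic is computed by the module functions; this orchestrator only
#' routes data.
#'
#' @param tree A \code{phylo}, or a path to a Newick file.  Ignored when
#'   `sim` is given.
#' @param traits Trait data frame or CSV path.  Ignored when `sim` is
#'   given.
#' @param sim Optional [sim_config()]: generate the inputs instead.
#' @param trait_cols Trait columns to analyze (default: numeric columns).
#' @param n_maps Stochastic maps per trait (default 100).
#' @param n_reps_ses Randomizations for SES nulls (default 999).
#' @param n_perm_signal Permutations for the K test (default 1000).
#' @param seed Master seed; all stage seeds derive from it.
#' @param log_transform,standardize Trait preprocessing, see
#'   [prep_trait()].
#' @param out_dir Optional directory: writes `rates.csv`, `ses.csv`,
#'   `signal.csv`, `validation.csv`, `manifest.json`.
#' @return List of class `analysis_report`: `rates`, `ses`, `signal`
#'   (data frames), `validation`, `manifest`, `failed` (character vector
#'   of failed stages, normally empty).
#' @export
run_pipeline <- function(tree = NULL, traits = NULL, sim = NULL,
                         trait_cols = NULL,
                         n_maps = 100, n_reps_ses = 999,
                         n_perm_signal = 1000, seed = 1L,
                         log_transform = "auto", standardize = TRUE,
                         out_dir = NULL) {
  seed <- as.integer(seed)
  if (!is.null(sim)) {
    ds <- make_dataset(sim)
    tree <- ds$tree
    traits <- ds$traits
  } else {
    if (is.character(tree))
      tree <- read_newick(paste(readLines(tree), collapse = ""))
    if (is.character(traits)) traits <- read_trait_table(traits)
  }
  stopifnot(inherits(tree, "phylo"), is.data.frame(traits))
  if (is.null(trait_cols))
    trait_cols <- names(traits)[vapply(traits, is.numeric, logical(1))]

  validation <- validate_inputs(tree, traits, trait_cols)
  if (length(validation$only_in_tree) || length(validation$only_in_table))
    stop("species mismatch between tree and trait table; tree-only: ",
         length(validation$only_in_tree), ", table-only: ",
         length(validation$only_in_table), call. = FALSE)
  if (length(validation$bad_growth_form))
    stop("growth_form values outside {liana, tree}: ",
         paste(validation$bad_growth_form, collapse = ", "),
         call. = FALSE)

  tree <- resolve_polytomies(tree, seed = seed)
  gf <- stats::setNames(traits$growth_form, traits$species)
  failed <- character(0)
  rates_rows <- list(); ses_rows <- list(); signal_rows <- list()

  ## --- rate table: one state-dependent fit per trait -------------------
  for (i in seq_along(trait_cols)) {
    tr <- trait_cols[i]
    res <- tryCatch({
      y_raw <- stats::setNames(traits[[tr]], traits$species)
      y <- prep_trait(y_raw, log_transform, standardize)
      pruned <- prune_to(tree, names(y))
      mk <- fit_mk(pruned, gf[names(y)])
      ens <- sample_stochastic_maps(pruned, mk, gf[names(y)],
                                    n_maps = n_maps,
                                    seed = seed + 100L + i)
      pooled <- pool_over_maps(ens, y)
      rows <- lapply(names(pooled$sigma2), function(g) {
        data.frame(trait = tr, group = g,
                   sigma2 = unname(pooled$sigma2[g]),
                   ci_lo = pooled$ci[g, "lo"],
                   ci_hi = pooled$ci[g, "hi"],
                   sigma2_single = pooled$single$sigma2,
                   chisq = pooled$lrt$chisq, p = pooled$lrt$p,
                   n = sum(gf[names(y)] == g),
                   n_maps = pooled$n_maps, seed = seed)
      })
      do.call(rbind, rows)
    }, error = function(e) {
      warning("rate stage failed for ", tr, ": ", conditionMessage(e))
      NULL
    })
    if (is.null(res)) failed <- c(failed, paste0("rates:", tr))
    else rates_rows[[tr]] <- res
  }

  ## --- SES table: MPD on the pooled tree, MTD per trait ----------------
  ses_res <- tryCatch({
    D <- cophenetic_matrix(tree)
    rows <- list()
    for (j in seq_along(c("liana", "tree"))) {
      g <- c("liana", "tree")[j]
      r <- ses(D, names(gf)[gf == g], pool = rownames(D),
               n_reps = n_reps_ses, seed = seed + 200L + j,
               group_label = g)
      rows[[length(rows) + 1L]] <- ses_row(r, g, "MPD")
    }
    for (i in seq_along(trait_cols)) {
      tr <- trait_cols[i]
      y_raw <- stats::setNames(traits[[tr]], traits$species)
      Dt <- trait_distance(y_raw, standardize = TRUE)
      for (j in seq_along(c("liana", "tree"))) {
        g <- c("liana", "tree")[j]
        grp <- intersect(names(gf)[gf == g], rownames(Dt))
        r <- ses(Dt, grp, pool = rownames(Dt), n_reps = n_reps_ses,
                 seed = seed + 300L + 10L * i + j, group_label = g)
        rows[[length(rows) + 1L]] <- ses_row(r, g, paste0("MTD:", tr))
      }
    }
    do.call(rbind, rows)
  }, error = function(e) {
    warning("SES stage failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(ses_res)) failed <- c(failed, "ses")

  ## --- signal table: K and lambda per trait x group --------------------
  for (i in seq_along(trait_cols)) {
    tr <- trait_cols[i]
    for (j in seq_along(c("liana", "tree"))) {
      g <- c("liana", "tree")[j]
      res <- tryCatch({
        sp <- traits$species[traits$growth_form == g &
                               !is.na(traits[[tr]])]
        y <- prep_trait(stats::setNames(
          traits[[tr]][match(sp, traits$species)], sp),
          log_transform, standardize)
        s <- signal_tests(tree, y, n_perm = n_perm_signal,
                          seed = seed + 400L + 10L * i + j)
        data.frame(trait = tr, group = g, K = s$K, p_K = s$p_K,
                   lambda = s$lambda, p_lambda = s$p_lambda,
                   boundary = s$boundary, n = s$n,
                   n_perm = s$n_perm, seed = seed)
      }, error = function(e) {
        warning("signal stage failed for ", tr, "/", g, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) failed <- c(failed, paste0("signal:", tr, ":", g))
      else signal_rows[[paste(tr, g)]] <- res
    }
  }

  report <- structure(list(
    rates = if (length(rates_rows)) do.call(rbind, rates_rows) else NULL,
    ses = ses_res,
    signal = if (length(signal_rows)) do.call(rbind, signal_rows)
             else NULL,
    validation = validation,
    manifest = list(package = "lianevol",
                    version = as.character(utils::packageVersion("lianevol")),
                    r_version = paste(R.version$major, R.version$minor,
                                      sep = "."),
                    seed = seed, n_maps = n_maps,
                    n_reps_ses = n_reps_ses,
                    n_perm_signal = n_perm_signal,
                    log_transform = log_transform,
                    standardize = standardize,
                    n_species = length(tree$tip.label),
                    traits = trait_cols),
    failed = failed), class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

ses_row <- function(r, group, metric) {
  data.frame(group = group, metric = metric, n = r$n_taxa, obs = r$obs,
             null_mean = r$null_mean, null_sd = r$null_sd, z = r$z,
             p = r$p, n_reps = r$n_reps, seed = r$seed)
}

#' Write an analysis report to disk
#'
#' Emits `rates.csv`, `ses.csv`, `signal.csv`, `validation.csv` and a
#' JSON `manifest.json` carrying every setting needed to re-run the
#' pipeline bit-identically.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, f) if (!is.null(x))
    utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  wr(report$rates, "rates.csv")
  wr(report$ses, "ses.csv")
  wr(report$signal, "signal.csv")
  wr(report$validation$n_by_trait_group, "validation.csv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
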