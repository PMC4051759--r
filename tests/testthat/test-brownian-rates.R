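test_that("bm_loglik matches the closed-form bivariate normal", {
  C <- diag(2); dimnames(C) <- list(c("s01", "s02"), c("s01", "s02"))
  y <- c(s01 = 0, s02 = 2)
  expect_equal(bm_loglik(C, y, sigma2 = 1, mu = 1), -log(2 * pi) - 1,
               tolerance = 1e-12)
  ## likelihood vanishes as sigma2 -> infinity
  expect_lt(bm_loglik(C, y, sigma2 = 1e8, mu = 1),
            bm_loglik(C, y, sigma2 = 1, mu = 1))
  expect_lt(bm_loglik(C, y, sigma2 = 1e8, mu = 1), -15)
  expect_error(bm_loglik(C, y[1], sigma2 = 1, mu = 1), "dimension")
})

test_that("GLS-matrix likelihood equals the pruning (contrasts) oracle", {
  for (seed in 1:10) {
    tr <- random_tree(10, seed + 400, root_age = 60)
    y <- sim_bm(tr, 0.2, seed = seed)
    C <- vcv_matrix(tr)
    s2 <- 0.1 + 0.05 * seed; mu <- -0.3
    expect_equal(bm_loglik(C, y[rownames(C)], s2, mu),
                 oracle_bm_loglik_pruning(tr, y, s2, mu),
                 tolerance = 1e-8)
  }
})

test_that("fit_single_rate solves the two-tip star by hand", {
  st <- star_tree(2, depth = 1)
  y <- setNames(c(0, 2), st$tip.label)
  fit <- fit_single_rate(st, y)
  expect_equal(fit$mu, 1, tolerance = 1e-12)
  expect_equal(fit$sigma2, 1.0, tolerance = 1e-12)

  expect_warning(fit_single_rate(st, setNames(c(3, 3), st$tip.label)),
                 "zero variance")
})

test_that("fit_single_rate recovers the generating rate", {
  s2_hat <- vapply(1:200, function(r) {
    tr <- simulate_tree(100, 100, seed = 8000 + r)
    y <- sim_bm(tr, 0.1, seed = 8000 + r)
    fit_single_rate(tr, y)$sigma2
  }, numeric(1))
  expect_lt(abs(mean(s2_hat) - 0.1) / 0.1, 0.05)
})

test_that("fit_multi_rate degenerates to the single-rate fit on a one-state map", {
  tr <- random_tree(25, 31, root_age = 70)
  y <- sim_bm(tr, 0.15, seed = 6)
  mono <- list(tree = tr,
               maps = lapply(seq_len(nrow(tr$edge)), function(e)
                 setNames(tr$edge.length[e], "liana")))
  fm <- fit_multi_rate(mono, y)
  f1 <- fit_single_rate(tr, y)
  expect_equal(fm$loglik, f1$loglik, tolerance = 1e-6)
  expect_equal(unname(fm$sigma2["liana"]), f1$sigma2, tolerance = 1e-4)
  ## a state expected but absent from the map is an informative error
  expect_error(fit_multi_rate(mono, y,
                              expected_states = c("liana", "tree")),
               "absent")
})

test_that("swapping state labels swaps the fitted rates", {
  tr <- random_tree(30, 37, root_age = 80)
  sim <- simulate_discrete(tr, 0.02, seed = 12)
  if (length(unique(sim$tip_states)) < 2) stop("fixture needs 2 states")
  y <- simulate_bm_multirate(tr, sim$history,
                             c(liana = 0.3, tree = 0.05), seed = 13)
  map1 <- list(tree = tr, maps = sim$history)
  swap <- c(liana = "tree", tree = "liana")
  map2 <- list(tree = tr, maps = lapply(sim$history, function(s)
    setNames(s, unname(swap[names(s)]))))
  fm1 <- fit_multi_rate(map1, y)
  fm2 <- fit_multi_rate(map2, y)
  expect_equal(unname(fm1$sigma2["liana"]), unname(fm2$sigma2["tree"]),
               tolerance = 1e-6)
  expect_equal(unname(fm1$sigma2["tree"]), unname(fm2$sigma2["liana"]),
               tolerance = 1e-6)
  expect_equal(fm1$loglik, fm2$loglik, tolerance = 1e-8)
})

test_that("state-dependent fit matches brownie.lite on a shared map", {
  suppressMessages(requireNamespace("phytools"))
  tr <- simulate_tree(40, 100, seed = 2)
  sim <- simulate_discrete(tr, 0.02, seed = 3)
  y <- simulate_bm_multirate(tr, sim$history,
                             c(liana = 0.3, tree = 0.05), seed = 4)
  pm <- with_seed_quiet(1, phytools::make.simmap(
    tr, sim$tip_states, model = "ER", nsim = 1))
  bl <- quiet_brownie(pm, y[pm$tip.label])
  ours <- fit_multi_rate(list(tree = tr, maps = pm$maps), y)
  single <- fit_single_rate(tr, y)
  expect_equal(single$sigma2, bl$sig2.single, tolerance = 1e-4)
  expect_equal(single$loglik, bl$logL1, tolerance = 1e-4)
  expect_equal(unname(ours$sigma2[colnames(pm$mapped.edge)]),
               unname(bl$sig2.multiple), tolerance = 1e-3)
  expect_equal(ours$loglik, bl$logL.multiple, tolerance = 1e-4)
})

test_that("regime covariances sum to the full phylogenetic covariance", {
  tr <- random_tree(30, 41, root_age = 90)
  sim <- simulate_discrete(tr, 0.03, seed = 14)
  if (length(unique(sim$tip_states)) < 2) stop("fixture needs 2 states")
  fit <- fit_mk(tr, sim$tip_states)
  ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 10,
                                seed = 15)
  C <- vcv_matrix(tr)
  for (m in ens$maps) {
    Ck <- regime_covariance(m)
    S <- Reduce(`+`, Ck)[rownames(C), colnames(C)]
    expect_equal(S, C, tolerance = 1e-9)
    for (M in Ck) {
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-8 * max(abs(ev)))
    }
  }
})

test_that("the likelihood ratio test is zero for identical models", {
  tr <- random_tree(20, 43, root_age = 50)
  y <- sim_bm(tr, 0.1, seed = 16)
  f1 <- fit_single_rate(tr, y)
  fake_multi <- structure(list(sigma2 = c(liana = f1$sigma2,
                                          tree = f1$sigma2),
                               loglik = f1$loglik, single = f1),
                          class = "rate_fit_multi")
  lrt <- lrt_single_vs_multi(fake_multi)
  expect_equal(lrt$chisq, 0)
  expect_equal(lrt$p, 1)
  expect_equal(lrt$df, 1L)
})

test_that("profile CIs contain the estimate and cover the truth", {
  tr <- random_tree(30, 47, root_age = 60)
  y <- sim_bm(tr, 0.1, seed = 17)
  f1 <- fit_single_rate(tr, y)
  ci <- rate_ci(f1)
  expect_lt(ci["lo"], f1$sigma2)
  expect_gt(ci["hi"], f1$sigma2)

  ## coverage over 200 single-rate simulations (binomial band of 0.95)
  hits <- vapply(1:200, function(r) {
    trr <- simulate_tree(40, 80, seed = 9000 + r)
    yy <- sim_bm(trr, 0.1, seed = 9000 + r)
    cc <- rate_ci(fit_single_rate(trr, yy))
    cc["lo"] <= 0.1 && 0.1 <= cc["hi"]
  }, logical(1))
  expect_gte(sum(hits), 183)   # 190 +/- 3 SD of Binomial(200, 0.95)
  expect_lte(sum(hits), 198)
})

test_that("profile CIs widen as sample size decreases", {
  width <- function(n, seed) {
    tr <- simulate_tree(n, 80, seed = seed)
    y <- sim_bm(tr, 0.1, seed = seed)
    ci <- rate_ci(fit_single_rate(tr, y))
    (ci["hi"] - ci["lo"]) / fit_single_rate(tr, y)$sigma2
  }
  w20 <- mean(vapply(1:20, function(r) width(20, 10000 + r), numeric(1)))
  w100 <- mean(vapply(1:20, function(r) width(100, 10000 + r),
                      numeric(1)))
  expect_gt(w20, w100)
})

test_that("pooling over maps integrates mapping uncertainty", {
  tr <- random_tree(40, 53, root_age = 100)
  sim <- simulate_discrete(tr, 0.015, seed = 18)
  if (length(unique(sim$tip_states)) < 2) stop("fixture needs 2 states")
  y <- simulate_bm_multirate(tr, sim$history,
                             c(liana = 0.25, tree = 0.08), seed = 19)
  fit <- fit_mk(tr, sim$tip_states)
  ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 8,
                                seed = 20)
  pooled <- pool_over_maps(ens, y)
  per <- pooled$per_map
  for (st in colnames(per)) {
    expect_gte(pooled$sigma2[st], min(per[, st]))
    expect_lte(pooled$sigma2[st], max(per[, st]))
    expect_lt(pooled$ci[st, "lo"], pooled$sigma2[st])
    expect_gt(pooled$ci[st, "hi"], pooled$sigma2[st])
  }
  ## nesting: pooled multi-rate lnL never below the (shared) single fit
  expect_gte(pooled$loglik, pooled$single$loglik - 1e-6)

  ## an ensemble of identical maps reproduces the single-map fit
  ens1 <- ens
  ens1$maps <- ens$maps[c(1, 1, 1)]
  pooled1 <- pool_over_maps(ens1, y)
  fm <- fit_multi_rate(ens$maps[[1]], y)
  expect_equal(unname(pooled1$sigma2), unname(fm$sigma2),
               tolerance = 1e-6)
  expect_equal(pooled1$loglik, fm$loglik, tolerance = 1e-8)
  expect_equal(unname(pooled1$sigma2_sd), c(0, 0), tolerance = 1e-10)
})

test_that("across-map rate dispersion shrinks when histories are certain", {
  tr <- simulate_tree(60, 100, seed = 61)
  sd_of <- function(q, seed) {
    sim <- simulate_discrete(tr, q, seed = seed)
    if (length(unique(sim$tip_states)) < 2) return(NA_real_)
    y <- simulate_bm_multirate(tr, sim$history,
                               c(liana = 0.3, tree = 0.05),
                               seed = seed + 1)
    fit <- fit_mk(tr, sim$tip_states)
    ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 12,
                                  seed = seed + 2)
    mean(pool_over_maps(ens, y)$sigma2_sd / pool_over_maps(ens, y)$sigma2)
  }
  lo <- vapply(1:6, function(r) sd_of(0.003, 300 + r), numeric(1))
  hi <- vapply(1:6, function(r) sd_of(0.05, 600 + r), numeric(1))
  expect_lt(mean(lo, na.rm = TRUE), mean(hi, na.rm = TRUE))
})

test_that("trait preparation logs and standardizes as configured", {
  x <- c(a = 1, b = 10, c = 100, d = NA)
  z <- prep_trait(x, "auto")
  expect_true(attr(z, "logged"))
  expect_equal(unname(mean(z)), 0, tolerance = 1e-12)
  expect_equal(unname(sd(z)), 1, tolerance = 1e-12)
  neg <- c(a = -1, b = 2, c = 5)
  z2 <- prep_trait(neg, "auto", standardize = FALSE)
  expect_false(attr(z2, "logged"))
  expect_equal(as.numeric(z2), unname(neg), ignore_attr = TRUE)
  expect_error(prep_trait(neg, "yes"), "positive")
})
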