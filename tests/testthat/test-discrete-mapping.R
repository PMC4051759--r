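test_that("mk_loglik matches the closed-form two-tip calculation", {
  q <- 0.5; t_br <- 1
  two <- star_tree(2, depth = t_br)
  tips <- setNames(c("liana", "liana"), two$tip.label)
  p_same <- (1 + exp(-2 * q * t_br)) / 2
  expected <- log(0.5 * (p_same^2 + (1 - p_same)^2))
  expect_equal(mk_loglik(two, tips, q, prior = c(0.5, 0.5)), expected,
               tolerance = 1e-12)

  ## q -> 0 with identical tip states: logL -> log prior of that state
  expect_equal(mk_loglik(two, tips, 1e-12, prior = c(0.5, 0.5)),
               log(0.5), tolerance = 1e-6)

  ## unknown state errors
  bad <- setNames(c("shrub", "liana"), two$tip.label)
  expect_error(mk_loglik(two, bad, q), "shrub")
})

test_that("mk_loglik equals brute-force enumeration on 5-tip trees", {
  for (seed in 1:8) {
    tr <- random_tree(5, seed + 200, root_age = 40)
    q12 <- 0.01 * seed; q21 <- 0.035
    prior <- lianevol:::mk_stationary(q12, q21)
    sim <- simulate_discrete(tr, 0.03, seed = seed)
    ours <- mk_loglik(tr, sim$tip_states, q12, q21, prior)
    brute <- oracle_mk_brute(tr, sim$tip_states, q12, q21, prior)
    expect_equal(ours, brute, tolerance = 1e-10)
  }
})

test_that("fit_mk recovers the generating rate and is at an optimum", {
  q_true <- 0.02
  q_hat <- vapply(1:60, function(r) {
    tr <- simulate_tree(134, 150, seed = 300 + r)
    sim <- simulate_discrete(tr, q_true, seed = 300 + r)
    if (length(unique(sim$tip_states)) < 2) return(NA_real_)
    fit_mk(tr, sim$tip_states)$Q[1, 2]
  }, numeric(1))
  q_hat <- q_hat[!is.na(q_hat)]
  expect_gt(length(q_hat), 50)
  expect_lt(abs(median(q_hat) - q_true) / q_true, 0.25)

  ## optimality of the ML point
  tr <- simulate_tree(100, 150, seed = 777)
  sim <- simulate_discrete(tr, q_true, seed = 777)
  fit <- fit_mk(tr, sim$tip_states)
  qh <- fit$Q[1, 2]
  ll <- function(q) mk_loglik(tr, sim$tip_states, q, q,
                              prior = c(0.5, 0.5))
  expect_gte(fit$loglik, ll(qh / 2))
  expect_gte(fit$loglik, ll(qh * 2))

  ## ARD nests ER
  ard <- fit_mk(tr, sim$tip_states, model_form = "ARD")
  expect_gte(ard$loglik, fit$loglik - 1e-4)
  expect_lt(2 * (ard$loglik - fit$loglik), qchisq(0.999, 1))

  ## single observed state is unidentifiable
  mono <- setNames(rep("liana", 100), tr$tip.label)
  expect_error(fit_mk(tr, mono), "not identifiable")
})

test_that("stochastic maps are consistent histories", {
  tr <- random_tree(12, 9, root_age = 60)
  sim <- simulate_discrete(tr, 0.02, seed = 10)
  ## force both states if the draw was monomorphic
  if (length(unique(sim$tip_states)) < 2)
    sim$tip_states[1] <- setdiff(c("liana", "tree"), sim$tip_states[1])
  fit <- fit_mk(tr, sim$tip_states)
  ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 20,
                                seed = 11)
  expect_length(ens$maps, 20)
  for (m in ens$maps[1:5]) {
    ## durations sum to branch lengths
    expect_equal(vapply(m$maps, sum, numeric(1)), tr$edge.length,
                 tolerance = 1e-9)
    ## endpoint states match sampled node states; adjacent segments
    ## always differ in state
    for (e in seq_len(nrow(tr$edge))) {
      segs <- m$maps[[e]]
      expect_equal(names(segs)[1], m$node_states[tr$edge[e, 1]])
      expect_equal(names(segs)[length(segs)],
                   m$node_states[tr$edge[e, 2]])
      if (length(segs) > 1)
        expect_true(all(names(segs)[-1] != names(segs)[-length(segs)]))
    }
    ## tip states honored
    expect_equal(m$node_states[seq_len(12)],
                 unname(sim$tip_states[tr$tip.label]))
  }
  ## determinism
  ens2 <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 20,
                                 seed = 11)
  expect_identical(ens$maps[[7]]$maps, ens2$maps[[7]]$maps)
})

test_that("near-zero rate with uniform tips yields single-segment maps", {
  tr <- random_tree(8, 13)
  tips <- setNames(rep("liana", 8), tr$tip.label)
  model <- structure(list(states = c("liana", "tree"),
                          Q = matrix(c(-1e-9, 1e-9, 1e-9, -1e-9), 2, 2),
                          prior = c(0.5, 0.5), loglik = NA,
                          model_form = "ER", convergence = TRUE),
                     class = "mk_model")
  ens <- sample_stochastic_maps(tr, model, tips, n_maps = 5, seed = 3)
  for (m in ens$maps) {
    expect_true(all(vapply(m$maps, length, integer(1)) == 1L))
    expect_true(all(vapply(m$maps, names, character(1)) == "liana"))
  }
})

test_that("endpoint-conditioned branch paths have forced parity", {
  ## differing endpoints require an odd number of transitions, >= 1
  for (r in 1:50) {
    set.seed(900 + r)
    segs <- lianevol:::sample_branch_path(1L, 2L, t_e = 2,
                                          leave = c(0.4, 0.4),
                                          states = c("a", "b"),
                                          max_reject = 10000L)
    expect_true(length(segs) %% 2 == 0)   # odd transitions = even segments
    set.seed(1900 + r)
    segs2 <- lianevol:::sample_branch_path(1L, 1L, t_e = 2,
                                           leave = c(0.4, 0.4),
                                           states = c("a", "b"),
                                           max_reject = 10000L)
    expect_true(length(segs2) %% 2 == 1)
  }
  ## hopeless conditioning errors out at the attempt bound
  expect_error(lianevol:::sample_branch_path(1L, 2L, t_e = 1,
                                             leave = c(1e-9, 1e-9),
                                             states = c("a", "b"),
                                             max_reject = 50L),
               "rejected")
})

test_that("time in state on a branch matches the occupancy integral", {
  q <- 0.4; t_br <- 2
  t1 <- vapply(1:10000, function(r) {
    set.seed(30000 + r)
    segs <- lianevol:::sample_branch_path(1L, 2L, t_br, c(q, q),
                                          c("a", "b"), 10000L)
    sum(segs[names(segs) == "a"])
  }, numeric(1))
  expected <- oracle_time_in_state1(1L, 2L, t_br, q)
  se <- sd(t1) / sqrt(length(t1))
  expect_lt(abs(mean(t1) - expected), 3 * se)
})

test_that("root-state sampling frequency matches the pruning marginal", {
  tr <- random_tree(5, 17, root_age = 50)
  tips <- setNames(c("liana", "liana", "tree", "liana", "tree"),
                   tr$tip.label)
  fit <- fit_mk(tr, tips)
  marg <- lianevol:::mk_root_marginal(tr, tips, fit)
  ens <- sample_stochastic_maps(tr, fit, tips, n_maps = 10000, seed = 5)
  root <- length(tr$tip.label) + 1L
  freq <- mean(vapply(ens$maps, function(m)
    m$node_states[root] == "liana", logical(1)))
  se <- sqrt(marg[1] * (1 - marg[1]) / 10000)
  expect_lt(abs(freq - marg[1]), 3 * se)
})

test_that("state_times conserves branch lengths and totals", {
  tr <- random_tree(20, 23, root_age = 80)
  sim <- simulate_discrete(tr, 0.03, seed = 8)
  st <- state_times(list(tree = tr, maps = sim$history))
  expect_equal(rowSums(st$per_branch), tr$edge.length, tolerance = 1e-9)
  expect_equal(sum(st$total), sum(tr$edge.length), tolerance = 1e-9)

  toyt <- star_tree(2, 1)
  toy <- list(tree = toyt,
              maps = list(setNames(c(0.3, 0.7), c("liana", "tree")),
                          setNames(1, "tree")))
  stt <- state_times(toy)
  expect_equal(stt$per_branch[1, ], c(liana = 0.3, tree = 0.7))
  expect_equal(stt$per_branch[2, ], c(liana = 0, tree = 1))
})

test_that("posterior time-in-state tracks the true simulated history", {
  ## At q = 0.02 on a 150-Myr, 134-tip tree the deep history is only
  ## weakly identified, so the posterior mean is shrunk toward the
  ## stationary mix: tracking is strong but not near-perfect.  The
  ## correlation must be decisively positive, and the posterior itself
  ## is validated against phytools::make.simmap below.
  truth <- numeric(40); post <- numeric(40)
  kept <- logical(40)
  for (r in 1:40) {
    tr <- simulate_tree(134, 150, seed = 5000 + r)
    sim <- simulate_discrete(tr, 0.02, seed = 5000 + r)
    if (length(unique(sim$tip_states)) < 2) next
    kept[r] <- TRUE
    truth[r] <- state_times(list(tree = tr,
                                 maps = sim$history))$total["liana"]
    fit <- fit_mk(tr, sim$tip_states)
    ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 10,
                                  seed = 6000 + r)
    post[r] <- mean(vapply(ens$maps, function(m)
      state_times(m)$total["liana"], numeric(1)))
  }
  ct <- cor.test(truth[kept], post[kept], alternative = "greater")
  expect_gt(ct$estimate, 0.5)
  expect_lt(ct$p.value, 1e-4)
})

test_that("posterior time-in-state agrees with phytools::make.simmap", {
  suppressMessages(requireNamespace("phytools"))
  ours <- numeric(6); theirs <- numeric(6)
  for (r in 1:6) {
    tr <- simulate_tree(134, 150, seed = 5000 + r)
    sim <- simulate_discrete(tr, 0.02, seed = 5000 + r)
    fit <- fit_mk(tr, sim$tip_states)
    ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 20,
                                  seed = 1)
    ours[r] <- mean(vapply(ens$maps, function(m)
      state_times(m)$total["liana"], numeric(1)))
    pm <- with_seed_quiet(1, phytools::make.simmap(
      tr, sim$tip_states, model = "ER", nsim = 20, pi = "equal"))
    theirs[r] <- mean(vapply(pm, function(m)
      sum(m$mapped.edge[, "liana"]), numeric(1)))
  }
  ## same posterior up to Monte-Carlo error in 20-map means
  expect_lt(max(abs(ours - theirs) / theirs), 0.1)
  expect_gt(cor(ours, theirs), 0.95)
})

test_that("map ensembles serialize to JSON lines", {
  tr <- random_tree(6, 29)
  sim <- simulate_discrete(tr, 0.03, seed = 2)
  if (length(unique(sim$tip_states)) < 2)
    sim$tip_states[1] <- setdiff(c("liana", "tree"), sim$tip_states[1])
  fit <- fit_mk(tr, sim$tip_states)
  ens <- sample_stochastic_maps(tr, fit, sim$tip_states, n_maps = 3,
                                seed = 4)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_map_ensemble(ens, f)
  lines <- readLines(f)
  expect_length(lines, 3)
  rec <- jsonlite::fromJSON(lines[1], simplifyVector = FALSE)
  expect_length(rec$branches, nrow(tr$edge))
  tot <- sum(vapply(rec$branches, function(b)
    sum(vapply(b, function(s) s$duration, numeric(1))), numeric(1)))
  expect_equal(tot, sum(tr$edge.length), tolerance = 1e-9)
})
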