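cycle3 <- function() {
  signaling_network(
    data.frame(id = c("A", "B")), data.frame(id = c("r1", "r2")),
    data.frame(source = c("A", "r1", "B", "r2"),
               target = c("r1", "B", "r2", "A"),
               kind = c("reactant", "product", "reactant", "product")))
}

test_that("flow roles follow product in-degree and reactant out-degree", {
  r <- assign_roles(chain_network(2))
  expect_equal(r$role[r$id == "A"], "source")
  expect_equal(r$role[r$id == "B"], "sink")

  r <- assign_roles(cycle3())
  expect_equal(unique(r$role), "internal")

  r <- assign_roles(crkl_motif())
  expect_equal(r$id[r$role == "source"], "ABL1")
  expect_setequal(r$id[r$role == "sink"], c("RHOQ", "RAP1B"))

  # a species touching no flow edge is isolated (both source and sink)
  net <- signaling_network(
    data.frame(id = c("A", "B", "X")), data.frame(id = "r"),
    data.frame(source = c("A", "r"), target = c("r", "B"),
               kind = c("reactant", "product")))
  r <- assign_roles(net)
  expect_equal(r$role[r$id == "X"], "isolated")
})

test_that("initial tokens implement the three scenarios", {
  net <- crkl_motif()
  for (tk in c(control = 100L, down = 10L, up = 500L)) {
    st <- init_tokens(net, spn_config("CRKL", seed_tokens = tk))
    expect_equal(unname(st["CRKL"]), tk)
    expect_equal(unname(st["ABL1"]), 100L)  # source assignment
    expect_equal(unname(st[c("PXN", "RAPGEF1", "RHOQ", "RAP1B")]),
                 rep(0L, 4))
  }
  # the seed assignment overrides the role-based one when the seed is a
  # source
  st <- init_tokens(chain_network(2), spn_config("A", seed_tokens = 500L))
  expect_equal(unname(st), c(500L, 0L))
  expect_error(init_tokens(net, spn_config("NOPE")), "NOPE")
})

test_that("a firing moves k ~ Uniform{0..min reactant tokens}", {
  net <- chain_network(2)
  st <- c(A = 2L, B = 0L)
  set.seed(1)
  draws <- replicate(3000, fire_transition(st, "r1", net)[["B"]])
  expect_setequal(sort(unique(draws)), 0:2)
  # E[k] = 1 under Uniform{0,1,2}; sd = sqrt(2/3)
  se <- sqrt(2 / 3) / sqrt(3000)
  expect_lt(abs(mean(draws) - 1), 3 * se)
  # conservation for one reactant, one product
  set.seed(2)
  out <- fire_transition(st, "r1", net)
  expect_equal(sum(out), sum(st))
  expect_true(all(out >= 0))
})

test_that("empty reactant places and closed gates freeze the firing", {
  net <- chain_network(2)
  expect_equal(fire_transition(c(A = 0L, B = 5L), "r1", net),
               c(A = 0L, B = 5L))

  gated <- signaling_network(
    data.frame(id = c("A", "M", "B")), data.frame(id = "r"),
    data.frame(source = c("A", "M", "r"), target = c("r", "r", "B"),
               kind = c("reactant", "modifier", "product")))
  # activating modifier below threshold: no change even with reactants
  expect_equal(fire_transition(c(A = 5L, M = 0L, B = 0L), "r", gated),
               c(A = 5L, M = 0L, B = 0L))
  # at threshold the gate opens; the modifier place is never consumed
  set.seed(3)
  out <- fire_transition(c(A = 5L, M = 1L, B = 0L), "r", gated)
  expect_equal(unname(out["M"]), 1L)
  expect_equal(unname(out["A"] + out["B"]), 5L)

  inhib <- signaling_network(
    data.frame(id = c("A", "M", "B")), data.frame(id = "r"),
    data.frame(source = c("A", "M", "r"), target = c("r", "r", "B"),
               kind = c("reactant", "modifier", "product"),
               sign = c("activating", "inhibiting", "activating")))
  # inhibiting modifier at/above threshold blocks
  expect_equal(fire_transition(c(A = 5L, M = 1L, B = 0L), "r", inhib),
               c(A = 5L, M = 1L, B = 0L))
  set.seed(4)
  out <- fire_transition(c(A = 5L, M = 0L, B = 0L), "r", inhib)
  expect_equal(unname(out["A"] + out["B"]), 5L)
})

test_that("a step on the all-zero state stays zero", {
  net <- crkl_motif()
  z <- setNames(integer(6), net$species$id)
  set.seed(5)
  expect_equal(spn_step(z, net), z)
})

test_that("sinks lose d ~ Uniform{0..own tokens} per step", {
  # single isolated species holding 2 tokens, no reactions: pure sink decay
  net <- signaling_network(data.frame(id = "S"), data.frame(),
                           data.frame())
  set.seed(6)
  draws <- replicate(3000, spn_step(c(S = 2L), net)[["S"]])
  expect_setequal(sort(unique(draws)), 0:2)
  se <- sqrt(2 / 3) / sqrt(3000)
  expect_lt(abs(mean(draws) - 1), 3 * se)
})

test_that("runs are deterministic given rng_seed and run index", {
  net <- crkl_motif()
  cfg <- spn_config("CRKL", n_runs = 5, n_timepoints = 10, rng_seed = 42)
  expect_identical(simulate_run(net, cfg, run = 3),
                   simulate_run(net, cfg, run = 3))
  expect_false(identical(simulate_run(net, cfg, run = 1),
                         simulate_run(net, cfg, run = 2)))
  # n_timepoints = 0: only the initial state
  cfg0 <- spn_config("CRKL", n_timepoints = 0)
  tr <- simulate_run(net, cfg0)
  expect_equal(nrow(tr), 1)
  expect_equal(tr["t0", ], init_tokens(net, cfg0))
})

test_that("ensembles are bit-identical under the same config and match
           their individual runs", {
  net <- crkl_motif()
  cfg <- spn_config("CRKL", n_runs = 20, n_timepoints = 5, rng_seed = 9)
  e1 <- simulate_ensemble(net, cfg)
  e2 <- simulate_ensemble(net, cfg)
  expect_identical(e1$mean, e2$mean)
  expect_identical(e1$variance, e2$variance)

  runs <- lapply(1:20, function(i) simulate_run(net, cfg, run = i))
  mu_t5 <- Reduce(`+`, lapply(runs, function(r) r["t5", ])) / 20
  expect_equal(unname(e1$mean[, "t5"]), unname(mu_t5[rownames(e1$mean)]))
})

test_that("time zero is deterministic: mean exact, variance zero", {
  net <- crkl_motif()
  cfg <- spn_config("CRKL", seed_tokens = 500L, n_runs = 30,
                    n_timepoints = 3)
  e <- simulate_ensemble(net, cfg)
  expect_equal(e$mean[, "t0"],
               structure(as.numeric(init_tokens(net, cfg)),
                         names = rownames(e$mean)))
  expect_true(all(e$variance[, "t0"] == 0))
})

test_that("token counts stay non-negative integers at all times", {
  gen <- generate_network(15, 12, p_modifier = 0.3, core_cycle_len = 3,
                          rng_seed = 21)
  cfg <- spn_config(gen$truth$seed, n_runs = 10, n_timepoints = 15,
                    rng_seed = 13)
  for (i in 1:10) {
    tr <- simulate_run(gen$network, cfg, run = i)
    expect_true(all(tr >= 0))
    expect_true(is.integer(tr))
  }
})

test_that("ensemble means match exact Markov enumeration on a miniature", {
  net <- chain_network(2)
  cfg <- spn_config("A", seed_tokens = 3L, source_tokens = 3L,
                    n_runs = 4000, n_timepoints = 2, rng_seed = 8)
  exact <- oracle_exact_means(net, c(A = 3L, B = 0L), steps = 2)
  e <- simulate_ensemble(net, cfg)
  for (tp in c("t1", "t2")) {
    for (sp in c("A", "B")) {
      se <- sqrt(e$variance[sp, tp] / e$n_runs)
      expect_lt(abs(e$mean[sp, tp] - exact[tp, sp]), 3 * se + 1e-12)
    }
  }
})

test_that("raising seed tokens never lowers downstream final means
           (activation-only network)", {
  net <- crkl_motif()
  finals <- sapply(c(10, 100, 500), function(tk) {
    e <- simulate_ensemble(net, spn_config("CRKL", seed_tokens = tk,
                                           n_runs = 200, rng_seed = 31))
    e$mean[, "t20"]
  })
  down <- c("CRKL", "PXN", "RAPGEF1", "RHOQ", "RAP1B")
  # allow 3 Monte-Carlo standard errors of slack on each comparison
  slack <- 3 * sqrt(apply(sapply(c(10, 100, 500), function(tk)
    simulate_ensemble(net, spn_config("CRKL", seed_tokens = tk,
                                      n_runs = 200,
                                      rng_seed = 31))$variance[, "t20"]),
    1, max) / 200)
  expect_true(all(finals[down, 2] >= finals[down, 1] - slack[down]))
  expect_true(all(finals[down, 3] >= finals[down, 2] - slack[down]))
})

test_that("mean trajectories stabilise over the last five time points", {
  e <- simulate_ensemble(crkl_motif(),
                         spn_config("CRKL", n_runs = 500, rng_seed = 17))
  mu <- e$mean
  peak <- apply(mu, 1, max)
  for (t in 16:20) {
    step_change <- abs(mu[, paste0("t", t)] - mu[, paste0("t", t - 1)])
    expect_true(all(step_change < 0.05 * peak))
  }
})
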