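test_that("the t statistic reproduces direct arithmetic", {
  # (10 - 14) / sqrt(100/500 + 100/500) = -4 / sqrt(0.4)
  expect_equal(t_value(10, 100, 14, 100, 500), -4 / sqrt(0.4),
               tolerance = 1e-12)
  expect_equal(round(t_value(10, 100, 14, 100, 500), 4), -6.3246)
  # identical means: zero regardless of variances
  expect_equal(t_value(5, 3, 5, 8, 100), 0)
  # doubling both variances divides |t| by sqrt(2)
  t1 <- t_value(10, 100, 14, 100, 500)
  t2 <- t_value(10, 200, 14, 200, 500)
  expect_equal(abs(t1) / abs(t2), sqrt(2), tolerance = 1e-12)
  # degenerate: both variances zero
  expect_equal(t_value(3, 0, 3, 0, 10), 0)
  expect_equal(t_value(5, 0, 3, 0, 10), Inf)
  expect_equal(t_value(3, 0, 5, 0, 10), -Inf)
})

test_that("p values and critical values match the t distribution", {
  expect_equal(round(p_value(2.51, df = 998), 3), 0.012)
  expect_equal(round(p_value(1.7, df = 998), 3), 0.089)
  expect_equal(p_value(0), 1)
  # monotone decreasing in |t|, symmetric in sign
  ts <- seq(0, 5, by = 0.25)
  expect_true(all(diff(p_value(ts, 998)) < 0))
  expect_equal(p_value(-2.3, 100), p_value(2.3, 100))

  expect_equal(round(critical_value(0.05, 500), 3), 1.965)
  expect_equal(critical_value(0.05, 1e7), 1.96, tolerance = 1e-3)
})

test_that("critical values agree with an independent quantile routine", {
  # invert the distribution function numerically instead of using qt()
  invert <- function(alpha, df) {
    uniroot(function(q) 2 * pt(q, df, lower.tail = FALSE) - alpha,
            c(0, 100), tol = 1e-10)$root
  }
  for (alpha in c(0.05, 0.01)) {
    for (df in c(500, 998)) {
      expect_equal(critical_value(alpha, df), invert(alpha, df),
                   tolerance = 1e-7)
    }
  }
})

motif_pair <- function(seed_tokens, n_runs = 300, rng = 100) {
  net <- crkl_motif()
  list(
    net = net,
    control = simulate_ensemble(net, spn_config("CRKL", seed_tokens = 100L,
                                                n_runs = n_runs,
                                                rng_seed = rng)),
    pert = simulate_ensemble(net, spn_config("CRKL",
                                             seed_tokens = seed_tokens,
                                             n_runs = n_runs,
                                             rng_seed = rng + 1))
  )
}

test_that("self-comparison yields zero statistics and no calls", {
  m <- motif_pair(10, n_runs = 50)
  s <- screen_perturbation(m$control, m$control, net = m$net)
  expect_true(all(s$t_value == 0))
  expect_true(all(!s$significant))
  expect_true(all(s$p_value == 1))
})

test_that("swapping control and perturbed negates t and preserves p", {
  m <- motif_pair(10, n_runs = 100)
  a <- screen_perturbation(m$control, m$pert, net = m$net)
  b <- screen_perturbation(m$pert, m$control, net = m$net)
  expect_equal(a$t_value, -b$t_value)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$significant, b$significant)
})

test_that("mismatched ensembles are a configuration error", {
  m <- motif_pair(10, n_runs = 50)
  other <- simulate_ensemble(chain_network(2),
                             spn_config("A", n_runs = 50))
  expect_error(screen_perturbation(m$control, other), "species")
  shorter <- simulate_ensemble(m$net, spn_config("CRKL", n_runs = 30))
  expect_error(screen_perturbation(m$control, shorter), "runs")
})

test_that("knockdown flags the seed and its strict descendants, not the
           pure-upstream source", {
  m <- motif_pair(10, n_runs = 500)
  s <- screen_perturbation(m$control, m$pert, net = m$net)
  down <- c("CRKL", "PXN", "RAPGEF1", "RHOQ", "RAP1B")
  expect_true(all(s$significant[s$id %in% down]))
  expect_false(s$significant[s$id == "ABL1"])
  # ABL1 never moves: degenerate zero-variance comparison, equal means
  expect_equal(s$t_value[s$id == "ABL1"], 0)
})

test_that("inactive species are excluded from the report, kept in raw
           output", {
  net <- crkl_motif()
  net$species$state[net$species$id == "PXN"] <- "inactive"
  c0 <- simulate_ensemble(net, spn_config("CRKL", n_runs = 50,
                                          rng_seed = 5))
  p0 <- simulate_ensemble(net, spn_config("CRKL", seed_tokens = 10L,
                                          n_runs = 50, rng_seed = 6))
  s <- screen_perturbation(c0, p0, net = net)
  expect_true("PXN" %in% s$id)
  expect_false(s$reported[s$id == "PXN"])
  s2 <- screen_perturbation(c0, p0, net = net,
                            test = test_config(active_only = FALSE))
  expect_true(s2$reported[s2$id == "PXN"])
})

test_that("a stronger perturbation yields larger |t| on strict
           descendants", {
  m_strong <- motif_pair(500, n_runs = 300, rng = 200)
  m_weak <- motif_pair(150, n_runs = 300, rng = 200)
  s_strong <- screen_perturbation(m_strong$control, m_strong$pert,
                                  net = m_strong$net)
  s_weak <- screen_perturbation(m_weak$control, m_weak$pert,
                                net = m_weak$net)
  down <- c("PXN", "RAPGEF1", "RHOQ", "RAP1B")
  expect_true(all(s_strong$abs_t[s_strong$id %in% down] >
                    s_weak$abs_t[s_weak$id %in% down]))
})

test_that("the combined results table has the report shape", {
  net <- crkl_motif()
  ctrl <- simulate_ensemble(net, spn_config("CRKL", n_runs = 120,
                                            rng_seed = 1))
  up <- simulate_ensemble(net, spn_config("CRKL", seed_tokens = 500L,
                                          n_runs = 120, rng_seed = 2))
  dn <- simulate_ensemble(net, spn_config("CRKL", seed_tokens = 10L,
                                          n_runs = 120, rng_seed = 3))
  s_up <- screen_perturbation(ctrl, up, net = net)
  s_dn <- screen_perturbation(ctrl, dn, net = net)
  tab <- results_table(s_up, s_dn)
  expect_equal(nrow(tab), 6)
  expect_equal(tab$name, sort(tab$name))
  expect_named(tab, c("name", "mean_control", "mean_up", "mean_down",
                      "t_up", "p_up", "sig_up", "t_down", "p_down",
                      "sig_down"))
  # control means pass straight through from the ensemble summary
  fin <- final_timepoint(ctrl)
  expect_equal(tab$mean_control[match(fin$id, tab$name)], fin$mean)
  # formatted output renders small p values "<0.001"
  fmt <- results_table(s_up, s_dn, formatted = TRUE)
  expect_true(any(grepl("<0.001", c(fmt$t_p_up, fmt$t_p_down))))
})

test_that("p-value formatting matches the report convention", {
  expect_equal(format_p(c(0.012, 0.0005, 0.089)),
               c("0.012", "<0.001", "0.089"))
})
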