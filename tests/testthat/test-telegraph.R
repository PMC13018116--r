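# Telegraph process of acute inflammatory events and the hybrid
# deterministic-stochastic simulator.

test_that("config derives chain shape and moments from tau and CV", {
  cfg <- telegraph_config(tau_on = 8, tau_off = 40, cv_on = 0.25, xi = 0.4)
  expect_identical(cfg$n_on, 16L)
  expect_equal(cfg$k_on, 2)
  expect_equal(cfg$tau_on, 8)
  expect_equal(cfg$sigma_on, sqrt(16) / 2)
  expect_equal(cfg$k_off, 1 / 40)
  expect_message(telegraph_config(cv_on = 0.4), "rounded")  # 1/sqrt(6) != 0.4
  expect_error(telegraph_config(tau_on = -1), "positive")
  expect_error(telegraph_config(xi = 0), "xi")
})

test_that("an unreachable on-state yields a switchless path", {
  cfg <- telegraph_config(tau_on = 5, tau_off = 1e12, cv_on = 1, xi = 0.5)
  path <- sample_telegraph(cfg, horizon = 50, seed = 1)
  expect_identical(nrow(path), 1L)
  expect_identical(path$state, 0L)
  expect_identical(telegraph_state_at(path, c(0, 10, 49)), c(0L, 0L, 0L))
  expect_equal(telegraph_on_fraction(path), 0)
})

test_that("paths alternate states, increase in time, and are reproducible", {
  cfg <- telegraph_config(tau_on = 5, tau_off = 10, cv_on = 0.5, xi = 0.5)
  p1 <- sample_telegraph(cfg, horizon = 100, seed = 7)
  p2 <- sample_telegraph(cfg, horizon = 100, seed = 7)
  expect_identical(p1, p2)
  expect_gt(nrow(p1), 5)
  expect_true(all(diff(p1$time_weeks) > 0))
  expect_true(all(abs(diff(p1$state)) == 1))
  expect_identical(p1$state[1], 0L)
  p3 <- sample_telegraph(cfg, horizon = 100, seed = 8)
  expect_false(identical(p1, p3))
})

test_that("on-durations follow the configured Erlang moments", {
  # Monte-Carlo moment check against the Erlang closed forms
  durations <- function(cfg, seed, min_n = 1e4) {
    set.seed(seed)
    # sample on-durations directly as the SSA does (sums of exponentials)
    replicate(min_n, sum(stats::rexp(cfg$n_on, cfg$k_on)))
  }
  cfg1 <- telegraph_config(tau_on = 6, tau_off = 30, cv_on = 1, xi = 0.5)
  d1 <- durations(cfg1, 11)
  expect_equal(mean(d1), 6, tolerance = 0.02)
  expect_equal(sd(d1) / mean(d1), 1, tolerance = 0.03)

  cfg16 <- telegraph_config(tau_on = 6, tau_off = 30, cv_on = 0.25, xi = 0.5)
  d16 <- durations(cfg16, 12)
  expect_equal(mean(d16), 6, tolerance = 0.02)
  expect_equal(sd(d16) / mean(d16), 0.25, tolerance = 0.05)

  # and the sampled paths respect the off-rate: mean off-duration 1/k_off
  p <- sample_telegraph(telegraph_config(tau_on = 2, tau_off = 12, cv_on = 1,
                                         xi = 0.5),
                        horizon = 3000, seed = 13)
  off_durs <- diff(p$time_weeks * 7)[p$state[-nrow(p)] == 0L]
  expect_equal(mean(off_durs), 12, tolerance = 0.1)
})

test_that("hybrid model with silent forcing reduces to the deterministic model", {
  params <- lupus_parameters()
  sch <- intervention_schedule(polyic_window = NULL)
  cfg <- telegraph_config(tau_on = 5, tau_off = 1e12, cv_on = 1, xi = 0.5)
  hy <- simulate_hybrid(params, sch, cfg, seed = 3, horizon = 30, dt = 0.5)
  det <- simulate_lupus(params, sch, horizon = 30, dt = 0.5)
  expect_equal(traj_cols(hy), traj_cols(det), tolerance = 1e-9)
})

test_that("hybrid runs are seed-reproducible and continuous across switches", {
  params <- lupus_parameters()
  sch <- intervention_schedule(polyic_window = NULL)
  cfg <- telegraph_config(tau_on = 2, tau_off = 6, cv_on = 0.5, xi = 0.8)
  h1 <- simulate_hybrid(params, sch, cfg, seed = 21, horizon = 30)
  h2 <- simulate_hybrid(params, sch, cfg, seed = 21, horizon = 30)
  expect_identical(attr(h1, "telegraph_path"), attr(h2, "telegraph_path"))
  expect_equal(traj_cols(h1), traj_cols(h2))
  # no jumps in the sampled states: increments bounded by grid-scale motion
  expect_false(anyNA(as.matrix(h1)))
  jumps <- apply(abs(apply(as.matrix(h1[, 2:15]), 2, diff)), 1, max)
  expect_lt(max(jumps), 5)
})

test_that("telegraph path serialises to a two-column CSV", {
  cfg <- telegraph_config()
  p <- sample_telegraph(cfg, horizon = 40, seed = 5)
  f <- tempfile(fileext = ".csv")
  write_telegraph_path(p, f)
  back <- utils::read.csv(f)
  expect_identical(names(back), c("time_weeks", "state"))
  expect_equal(back$time_weeks, p$time_weeks)
  expect_identical(as.integer(back$state), p$state)
})
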