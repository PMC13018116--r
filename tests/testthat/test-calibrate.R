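# Calibration procedure and the behaviour of the shipped preset.

test_that("the shipped preset satisfies the deterministic constraints", {
  chk <- check_calibration(lupus_parameters(), deterministic_only = TRUE)
  expect_true(chk$ok[["two_peaks"]])
  expect_true(chk$ok[["first_peak_week"]])
  expect_true(chk$ok[["second_peak_week"]])
  expect_true(chk$ok[["wt_recovery"]])
  expect_true(chk$ok[["untreated_gap"]])
  expect_true(chk$ok[["zeta_ic"]])
  expect_identical(chk$score, 0)
})

test_that("calibration returns the immune-complex weights fixed at 0.2", {
  cal <- calibrate_defaults(seed = 1, n_candidates = 2)
  expect_equal(cal$params$zeta3, 0.2)
  expect_equal(cal$params$zeta5, 0.2)
  expect_identical(cal$check$score, 0)
})

test_that("calibration is deterministic given the seed", {
  # perturbed start forces an actual search; two runs must agree exactly
  start <- lupus_parameters(q2 = 1.86 * 1.04)
  c1 <- calibrate_defaults(start, seed = 5, n_candidates = 3)
  c2 <- calibrate_defaults(start, seed = 5, n_candidates = 3)
  expect_identical(unlist(c1$params[]), unlist(c2$params[]))
  expect_identical(c1$log, c2$log)
})

test_that("eliminating damage-induced interferon release further reduces damage", {
  params <- lupus_parameters(preset = "uniform")
  res <- feedback_knockout_scan(params,
                                knockout_sets = list(c("F3", "F5"),
                                                     c("F1", "F3", "F5")),
                                t_eval = 25, horizon = 26)
  expect_lt(res$damage[res$knockouts == "F1+F3+F5"],
            res$damage[res$knockouts == "F3+F5"])
})

test_that("reduced infiltration or increased removal prevents ESRD", {
  params <- lupus_parameters()
  ref <- esrd_reference(params)
  sens <- sensitivity_scan(params, parameters = c("beta", "delta"), ref = ref)
  expect_true(sens$censored[sens$parameter == "beta" & sens$direction == "down"])
  expect_true(sens$censored[sens$parameter == "delta" & sens$direction == "up"])
})

test_that("damage by week 25 responds monotonically to the stimulus level", {
  d25 <- vapply(c(0.3, 0.5, 0.66, 0.85), function(q1) {
    p <- lupus_parameters(q1 = q1)
    tr <- simulate_lupus(p, intervention_schedule(), horizon = 26)
    max(tr$x8[tr$time_weeks <= 25])
  }, numeric(1))
  expect_true(all(diff(d25) > 0))
})

test_that("hybrid onset fraction does not decrease with event strength", {
  params <- lupus_parameters()
  f <- vapply(c(0.06, 0.13, 0.3), function(xi) {
    hybrid_pre_esrd_fraction(params, telegraph_config(xi = xi),
                             n = 60, seed = 9)$fraction
  }, numeric(1))
  expect_true(all(diff(f) >= 0))
})
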