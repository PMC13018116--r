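# Outcome definitions on controlled synthetic trajectories: threshold
# crossings, censoring, classification and the stochastic onset delay.

fake_ref <- function(esrd = 2, week = 28) {
  structure(list(esrd_value = esrd, pre_esrd_value = 0.7 * esrd,
                 esrd_week = week, max_damage = esrd / 0.95, horizon = 60),
            class = "esrd_reference")
}

ramp_traj <- function(weeks, x8) {
  structure(data.frame(time_weeks = weeks, x8 = x8),
            class = c("lupus_trajectory", "data.frame"))
}

test_that("time_to_esrd interpolates the first crossing linearly", {
  ref <- fake_ref(esrd = 2)
  tr <- ramp_traj(seq(12, 40, 1), seq(0, 28, 1) * 0.1)  # x8 = 0.1 (t - 12)
  tt <- time_to_esrd(tr, ref)
  expect_false(tt$censored)
  expect_equal(tt$week, 12 + 2 / 0.1)
  # all-zero damage is censored
  tt0 <- time_to_esrd(ramp_traj(seq(12, 40, 1), rep(0, 29)), ref)
  expect_true(tt0$censored)
  expect_true(is.na(tt0$week))
})

test_that("pre-ESRD precedes ESRD on any increasing trajectory", {
  ref <- fake_ref(esrd = 2)
  tr <- ramp_traj(seq(12, 40, 0.5), (seq(12, 40, 0.5) - 12)^1.5 * 0.02)
  t_pre <- lupusim:::crossing_week(tr, ref$pre_esrd_value)
  t_esrd <- lupusim:::crossing_week(tr, ref$esrd_value)
  expect_lt(t_pre, t_esrd)
  expect_true(pre_esrd_at(tr, ref, t_eval = t_pre + 0.6))
  expect_false(pre_esrd_at(tr, ref, t_eval = t_pre - 0.6))
  expect_error(pre_esrd_at(tr, ref, t_eval = 45), "outside")
})

test_that("censored ESRD can still carry a positive pre-ESRD flag", {
  ref <- fake_ref(esrd = 2)
  # plateaus at 80% of the ESRD value: pre-ESRD yes, ESRD never
  tr <- ramp_traj(seq(12, 40, 0.5), pmin((seq(12, 40, 0.5) - 12) * 0.2, 1.6))
  expect_true(time_to_esrd(tr, ref)$censored)
  expect_true(pre_esrd_at(tr, ref, t_eval = 30))
})

test_that("t_stoch subtracts the reference time and respects censoring", {
  ref <- fake_ref(esrd = 2, week = 28)
  tr <- ramp_traj(seq(12, 60, 0.5), (seq(12, 60, 0.5) - 12) * 2 / 28)
  # crosses 2 at week 12 + 28 = 40 => t_stoch = 12
  expect_equal(t_stoch(tr, ref)$weeks, 12, tolerance = 1e-6)
  flat <- ramp_traj(seq(12, 60, 0.5), rep(0.1, 97))
  ts <- t_stoch(flat, ref)
  expect_true(ts$censored)
  expect_true(is.na(ts$weeks))
})

test_that("the reference is self-consistent on the default run", {
  params <- lupus_parameters()
  ref <- esrd_reference(params)
  expect_equal(ref$esrd_value, 0.95 * ref$max_damage)
  expect_equal(ref$pre_esrd_value, 0.7 * ref$esrd_value)
  tr <- simulate_lupus(params, intervention_schedule(), horizon = ref$horizon)
  tt <- time_to_esrd(tr, ref)
  expect_false(tt$censored)
  expect_equal(tt$week, ref$esrd_week, tolerance = 1e-6)
  # the reference run crosses its pre-ESRD value before its ESRD value
  expect_lt(lupusim:::crossing_week(tr, ref$pre_esrd_value), ref$esrd_week)
})

test_that("interferon peak finder handles plateaus and boundary maxima", {
  tr <- structure(data.frame(
    time_weeks = seq(0, 10, 0.5),
    c = c(0.1, 0.3, 0.6, 0.6, 0.6, 0.4, 0.2, 0.1, 0.1, 0.2, 0.3,
          0.5, 0.6, 0.7, 0.8, 0.85, 0.9, 0.92, 0.94, 0.95, 0.96)),
    class = c("lupus_trajectory", "data.frame"))
  pk <- ifn_peaks(tr)
  expect_identical(nrow(pk), 2L)
  expect_equal(pk$week[1], 1)      # first point of the plateau
  expect_equal(pk$week[2], 10)     # still rising at the stop
  expect_equal(pk$value, c(0.6, 0.96))
  flat <- structure(data.frame(time_weeks = 0:10, c = rep(0.2, 11)),
                    class = c("lupus_trajectory", "data.frame"))
  expect_identical(nrow(ifn_peaks(flat)), 0L)
})
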