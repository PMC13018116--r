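# The specific disease model: parameter record, interferon level, and the
# right-hand side against an independent transcription oracle.

test_that("default parameters carry the literature-anchored rates", {
  p <- lupus_parameters("NZBW")
  expect_equal(p$gamma, 2.4)
  expect_equal(p$delta, 0.24)
  expect_equal(p$beta, 2.4)
  expect_equal(p$alpha, 4.8)
  expect_equal(p$lambda, 14.4)
  expect_equal(p$q, 1.44)
  expect_equal(p$eta, 0.24)
  expect_equal(p$mu1, 1 / 42)
  expect_equal(p$zeta3, 0.2)
  expect_equal(p$zeta5, 0.2)
  wt <- lupus_parameters("WT")
  expect_identical(wt$mu2, 0)
  expect_equal(wt[setdiff(names(unlist(wt)), "mu2")],
               p[setdiff(names(unlist(p)), "mu2")])
  expect_error(lupus_parameters(nonsense = 2), "unknown parameter")
})

test_that("feedback knockouts zero the mapped weights", {
  p <- lupus_parameters(preset = "uniform")
  expect_identical(apply_feedback_knockout(p, character()), p)
  ko <- apply_feedback_knockout(p, c("F3", "F4", "F5"))
  expect_identical(ko$zeta3, 0)
  expect_identical(ko$zeta4, 0)
  expect_identical(ko$zeta5, 0)
  expect_identical(ko$zeta1, p$zeta1)
  expect_error(apply_feedback_knockout(p, "F9"), "unknown feedback")
})

test_that("interferon level follows its quasi-steady-state expression", {
  p <- lupus_parameters()
  s <- intervention_schedule()           # poly(I:C) weeks 19-23
  # all drives vanish outside the window
  expect_equal(ifn_level(10, 0, 0, p, s), p$q0)
  # cap binds when baseline + stimulus exceed 1
  p_hot <- lupus_parameters(q0 = 0.3, q1 = 0.9)
  expect_identical(ifn_level(20, 0, 0, p_hot, s), 1)
  # hand evaluation at half-saturation: h(K2, K2) = 1/2
  v <- ifn_level(20, p$K2, p$K2, p, s)
  expect_equal(v, min(p$q0 + p$q1 + p$q2 * (p$zeta4 + p$zeta1) / 2, 1))
  # knocking out F1/F4 removes the damage/immune-complex terms
  s_ko <- intervention_schedule(feedback_knockouts = c("F1", "F4"))
  expect_equal(ifn_level(10, 5, 5, p, s_ko), p$q0)
})

test_that("rhs limiting cases: zero effectors and saturated epithelium", {
  p <- lupus_parameters()
  s <- intervention_schedule()
  st <- stats::setNames(numeric(13 + p$n_ic), lupusim:::state_names(p))
  d <- lupus_rhs(100, st, p, s)    # before the window, everything at zero
  expect_identical(unname(d["x3"]), 0)   # hill of zero gates the influx
  expect_identical(unname(d["x5"]), 0)
  st2 <- st
  st2["x4"] <- p$omega
  d2 <- lupus_rhs(100, st2, p, s)  # at capacity the logistic factor is zero
  expect_equal(unname(d2["x4"]), -p$delta * p$omega)
})

test_that("rhs equals an independent transcription of the model equations", {
  # oracle_rhs (helper-oracle.R) is a term-by-term transcription of the
  # model table, maintained independently of the implementation
  set.seed(99)
  p <- lupus_parameters()
  s <- intervention_schedule()
  for (t in c(100, 140, 200)) {        # outside, inside, after the window
    st <- stats::runif(13 + p$n_ic, 0, 2)
    got <- unname(lupus_rhs(t, st, p, s))
    want <- unname(oracle_rhs(t, st, p, 19 * 7, 23 * 7))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # with depletion of both compartments active
  s_dep <- intervention_schedule(depletion_targets = c("tILC", "vNK"))
  st <- stats::runif(13 + p$n_ic, 0, 2)
  got <- unname(lupus_rhs(20 * 7, st, p, s_dep))
  want <- unname(oracle_rhs(20 * 7, st, p, 19 * 7, 23 * 7,
                            m_tilc = 0.2, m_vnk = 0.2))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("compiled and R right-hand sides produce the same trajectories", {
  p <- lupus_parameters()
  s <- intervention_schedule()
  tr_c <- simulate_lupus(p, s, horizon = 30, dt = 0.5, use_compiled = TRUE)
  tr_r <- simulate_lupus(p, s, horizon = 30, dt = 0.5, use_compiled = FALSE)
  expect_lt(max(abs(as.matrix(tr_c[, -1]) - as.matrix(tr_r[, -1]))), 1e-5)
})

test_that("initial state is a homeostatic start, not the degenerate zero", {
  p <- lupus_parameters()
  s <- intervention_schedule()
  st <- initial_state(p, s)
  expect_gt(st[["x1"]], 0)
  expect_true(all(st[setdiff(names(st), "x1")] == 0))
  d <- lupus_rhs(12 * 7, st, p, s)
  expect_lt(abs(d[["x1"]]), 1e-6)
  expect_error(initial_state(p, s, seed_fraction = 0), "degenerate")
  # the burn-in result does not depend on the seed magnitude
  st2 <- initial_state(p, s, seed_fraction = 0.3)
  expect_equal(st[["x1"]], st2[["x1"]], tolerance = 1e-7)
})

test_that("genotypes differ only through immune-complex terms at start", {
  p_n <- lupus_parameters("NZBW")
  s_n <- intervention_schedule()
  s_w <- intervention_schedule(genotype = "WT")
  st_n <- initial_state(p_n, s_n)
  st_w <- initial_state(p_n, s_w)
  expect_equal(st_n, st_w)   # identical homeostatic start
  tr_n <- simulate_lupus(p_n, s_n, horizon = 16, dt = 0.5)
  tr_w <- simulate_lupus(p_n, s_w, horizon = 16, dt = 0.5)
  shared <- c("x4", "x7")    # epithelium fills in identically early on
  expect_equal(tr_n[1:5, shared], tr_w[1:5, shared], tolerance = 1e-6)
  expect_true(all(tr_w$x9 == 0))
})

test_that("the default trajectory is converged in solver tolerance", {
  p <- lupus_parameters()
  s <- intervention_schedule()
  a <- simulate_lupus(p, s, horizon = 40, dt = 0.5)
  b <- simulate_lupus(p, s, horizon = 40, dt = 0.5,
                      rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-6)
})
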