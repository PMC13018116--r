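# Generic framework: assembly of coupled cell/cytokine systems from a
# declarative network description.

test_that("single species with logistic growth relaxes to its fixed point", {
  gam <- 2; del <- 0.5; om <- 1
  sp <- network_spec(list(
    cell_species("x", proliferation = list(rate = gam, drive = NULL),
                 capacity = om, death = del)))
  out <- simulate_network(sp, c(x = om / 2), seq(0, 40, 0.5))
  # gamma (1 - x*/omega) = delta  =>  x* = omega (1 - delta/gamma)
  expect_equal(tail(out$x, 1), om * (1 - del / gam), tolerance = 1e-7)
})

test_that("pure activation exchange conserves the total population", {
  sp <- network_spec(list(
    cell_species("a", activation = list(list(from = "b", rate = 1.2, drive = NULL))),
    cell_species("b", activation = list(list(from = "a", rate = 1.2, drive = NULL)))))
  out <- simulate_network(sp, c(a = 0.9, b = 0.1), seq(0, 10, 0.1))
  expect_equal(out$a + out$b, rep(1, nrow(out)), tolerance = 1e-8)
})

test_that("minimal two-cell one-cytokine motif matches a hand-coded oracle", {
  # Motif: m infiltrates gated by cytokine g, proliferates up to capacity;
  # f secretes g, m consumes it; f has plain logistic growth.
  K <- 0.4; beta <- 1.5; gam <- 1.8; del <- 0.3
  qs <- 1.1; lam <- 5; eta <- 0.4; om <- 1
  sp <- network_spec(
    cells = list(
      cell_species("m",
                   infiltration = list(rate = beta,
                                       drive = list(drive_term("g", K)),
                                       delay = NULL),
                   proliferation = list(rate = gam,
                                        drive = list(drive_term("g", K))),
                   capacity = om, death = del),
      cell_species("f", proliferation = list(rate = gam, drive = NULL),
                   capacity = om, death = del)),
    cytokines = list(
      cytokine_species("g", secretion = c(f = qs), endocytosis = c(m = lam),
                       K = K, degradation = eta)))

  oracle <- function(t, y, parms) {
    m <- y[1]; f <- y[2]; g <- y[3]
    h <- g^3 / (K^3 + g^3)
    dm <- beta * min(h, 1) + gam * min(h, 1) * (1 - m / om) * m - del * m
    df <- gam * (1 - f / om) * f - del * f
    dg <- qs * f - lam * h * m - eta * g
    list(c(dm, df, dg))
  }
  times <- seq(0, 30, 0.1)
  y0 <- c(m = 0, f = 0.05, g = 0)
  ours <- simulate_network(sp, y0, times, rtol = 1e-10, atol = 1e-12)
  ref <- deSolve::lsoda(unname(y0), times, oracle, NULL,
                        rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(as.matrix(ours[, c("m", "f", "g")]) - ref[, 2:4])), 1e-8)
})

test_that("states remain non-negative and capacities are respected", {
  set.seed(7)
  for (rep in 1:5) {
    om <- runif(1, 0.5, 2)
    sp <- network_spec(
      cells = list(
        cell_species("u",
                     infiltration = list(rate = runif(1, 0.5, 3),
                                         drive = list(drive_term("w", runif(1, 0.2, 1))),
                                         delay = delay_chain(runif(1, 0.2, 2),
                                                             sample(1:4, 1))),
                     death = runif(1, 0.1, 0.5)),
        cell_species("v", proliferation = list(rate = runif(1, 1, 3), drive = NULL),
                     capacity = om, death = runif(1, 0.1, 0.5))),
      cytokines = list(
        cytokine_species("w", secretion = c(v = runif(1, 0.5, 2)),
                         endocytosis = c(u = runif(1, 2, 8)),
                         K = runif(1, 0.2, 1), degradation = runif(1, 0.1, 0.5))))
    st <- c(u = 0, v = runif(1, 0, om), w = 0)
    out <- simulate_network(sp, st, seq(0, 60, 0.5))
    expect_true(all(as.matrix(out[, -1]) >= -1e-9))
    expect_true(all(out$v <= om + 1e-6))
  }
})

test_that("infiltration delays act with the Erlang lag", {
  # gated vs delayed infiltration: the delayed variant lags by ~n/k
  mk <- function(delay) network_spec(list(
    cell_species("x", infiltration = list(rate = 1, drive = NULL, delay = delay),
                 death = 1)))
  times <- seq(0, 30, 0.05)
  direct <- simulate_network(mk(NULL), c(x = 0), times)
  lagged <- simulate_network(mk(delay_chain(0.5, 4)), c(x = 0), times)
  # both settle at rate/death = 1, but the delayed one is slower
  expect_equal(tail(direct$x, 1), 1, tolerance = 1e-6)
  expect_equal(tail(lagged$x, 1), 1, tolerance = 1e-3)
  t_half <- function(df) df$time[which(df$x >= 0.5)[1]]
  expect_gt(t_half(lagged) - t_half(direct), 0.8 * delay_mean(delay_chain(0.5, 4)) - 2)
})

test_that("network validation reports every offending reference", {
  expect_error(
    network_spec(list(
      cell_species("a", infiltration = list(rate = 1,
                                            drive = list(drive_term("nope", 1)),
                                            delay = NULL))),
      list(cytokine_species("c1", secretion = c(ghost = 1), K = 1,
                            degradation = 0))),
    "nope.*|ghost.*")
  expect_error(
    network_spec(list(cell_species("a")),
                 list(cytokine_species("c1", secretion = c(a = 1), K = 1,
                                       degradation = 0))),
    "neither consumed nor degraded")
})

test_that("network specs round-trip through YAML losslessly", {
  sp <- network_spec(
    cells = list(
      cell_species("m",
                   infiltration = list(rate = 1.5,
                                       drive = list(drive_term("g", 0.4, 0.7)),
                                       delay = delay_chain(0.5, 3)),
                   proliferation = list(rate = 2, drive = list(drive_term("g", 0.4))),
                   capacity = 1.5, death = 0.3),
      cell_species("f", proliferation = list(rate = 2, drive = NULL),
                   capacity = 1, death = 0.3,
                   activation = list(list(from = "m", rate = 0.8,
                                          drive = list(drive_term("g", 0.2, 2)))))),
    cytokines = list(
      cytokine_species("g", secretion = c(f = 1.1), endocytosis = c(m = 5),
                       K = 0.4, degradation = 0.4)))
  f <- tempfile(fileext = ".yaml")
  write_network_spec(sp, f)
  sp2 <- read_network_spec(f)
  expect_equal(sp2, sp)
  # derivative functions agree on a random state
  nm <- network_state_names(sp)
  set.seed(1)
  st <- stats::setNames(runif(length(nm)), nm)
  expect_equal(assemble_rhs(sp2)(0, st)[[1]], assemble_rhs(sp)(0, st)[[1]])
})

test_that("unknown YAML keys are rejected with their location", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("cells:", "- name: a", "  deathh: 1"), f)
  expect_error(read_network_spec(f), "deathh")
})
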