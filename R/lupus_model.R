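# The specific lupus-nephritis model: nine named cell/tissue states, a
# damage-driven immune-complex delay chain, four tissue cytokines and an
# algebraic (quasi-steady-state) type-I interferon concentration.
#
# State layout (this ordering is part of the public contract):
#   x1 tILC-low, x2 tILC, x3 MOMA, x4 iPEC, x5 vNK, x6 MO, x7 cEC,
#   x8 damage, x9 immune complexes,
#   y1..y_n  immune-complex delay-chain intermediates (n = n_ic),
#   c1..c4   tissue cytokines.
# Internal time is measured in days (all rates are per day); the public
# interface reports weeks of age, with exactly 7 days per week.

DAYS_PER_WEEK <- 7

state_names <- function(params) {
  c(paste0("x", 1:9), paste0("y", seq_len(params$n_ic)), paste0("c", 1:4))
}

in_window <- function(t_days, window_weeks) {
  !is.null(window_weeks) &&
    t_days >= window_weeks[1] * DAYS_PER_WEEK &&
    t_days <= window_weeks[2] * DAYS_PER_WEEK
}

#' Quasi-steady-state type-I interferon concentration
#'
#' Interferon is modelled algebraically, reflecting its fast kinetics
#' relative to the cell populations:
#' `c = min(q0 + q1 * [poly(I:C) active] + q2 * (zeta4 h(x9, K2) + zeta1 h(x8, K2)), 1)`.
#' The baseline `q0`, the stimulus level `q1` (active while the schedule's
#' poly(I:C) window is open) and the feedback level `q2` are bounded
#' concentration levels; the total is capped at 1.
#'
#' @param t_weeks Time in weeks of age.
#' @param x8 Current tissue damage level.
#' @param x9 Current immune-complex level.
#' @param params A [lupus_parameters()] object.
#' @param schedule An [intervention_schedule()]; its `polyic_window` defines
#'   the stimulus indicator and its knockouts are honoured.
#' @return Concentration in `[0, 1]`.
#' @export
ifn_level <- function(t_weeks, x8, x9, params, schedule = intervention_schedule()) {
  p <- effective_parameters(params, schedule)
  ifn_level_days(t_weeks * DAYS_PER_WEEK, x8, x9, p, schedule$polyic_window)
}

ifn_level_days <- function(t_days, x8, x9, p, polyic_window) {
  stim <- if (in_window(t_days, polyic_window)) p$q1 else 0
  min(p$q0 + stim + p$q2 * (p$zeta4 * hill(x9, p$K2) + p$zeta1 * hill(x8, p$K2)), 1)
}

# Depletion multipliers at time t (days): 1 - kappa while the depletion
# window is active for the targeted compartment, 1 otherwise.
depletion_factors <- function(t_days, schedule) {
  m <- c(tILC = 1, vNK = 1)
  if (length(schedule$depletion_targets) &&
      in_window(t_days, schedule$depletion_window)) {
    m[schedule$depletion_targets] <- 1 - schedule$depletion_strength
  }
  # the capacity multiplier appears in a denominator; full depletion is
  # approximated by a 0.5% residual capacity
  m["tILC"] <- max(m[["tILC"]], 0.005)
  m
}

#' Right-hand side of the lupus-nephritis model
#'
#' Evaluates the time derivatives of the full state vector.  This is the
#' reference R implementation; [simulate_lupus()] uses an equivalent
#' compiled version for speed (their agreement is enforced by the test
#' suite).
#'
#' @param t_days Time in days (weeks of age times 7).
#' @param state Named or unnamed numeric state vector in the documented
#'   layout (`x1..x9`, `y1..y_n`, `c1..c4`).
#' @param params A [lupus_parameters()] object.
#' @param schedule An [intervention_schedule()].
#' @param x_on Telegraph-state forcing of immune-complex production (0 in
#'   the deterministic model; 0/1 in the hybrid model between switches).
#' @return Numeric vector of derivatives, same length and order as `state`.
#' @export
lupus_rhs <- function(t_days, state, params, schedule = intervention_schedule(),
                      x_on = 0) {
  p <- effective_parameters(params, schedule)
  n <- p$n_ic
  if (length(state) != 13L + n) {
    stop(sprintf("state has length %d, expected %d", length(state), 13L + n),
         call. = FALSE)
  }
  # adaptive solvers probe trial states slightly below zero; gates are
  # evaluated on the clamped state so such excursions stay transient
  state <- pmax(state, 0)
  x <- state[1:9]
  y <- state[9L + seq_len(n)]
  cc <- state[(10L + n):(13L + n)]
  dep <- depletion_factors(t_days, schedule)
  cifn <- ifn_level_days(t_days, x[8], x[9], p, schedule$polyic_window)

  act <- p$alpha * saturating_sum(c(hill(cifn, p$K1), p$zeta2 * hill(x[8], p$K2)))
  pool <- x[1] + x[2]
  dx1 <- p$gamma * (1 - pool / (p$omega * dep[["tILC"]])) * pool -
    act * x[1] - p$delta * x[1]
  dx2 <- act * x[1] - p$delta * x[2]
  dx3 <- p$beta * saturating_sum(c(hill(x[2], p$K2), p$zeta3 * hill(x[9], p$K2))) +
    p$gamma * hill(cc[2], p$K2) * x[3] - p$delta * x[3]
  dx4 <- (p$beta + p$gamma * hill(cc[1], p$K2) * x[4]) * (1 - x[4] / p$omega) -
    p$delta * x[4]
  dx5 <- p$beta * hill(x[6], p$K3) * dep[["vNK"]] - p$delta * x[5]
  dx6 <- p$beta * saturating_sum(c(p$zeta5 * hill(x[9], p$K2),
                                   p$vartheta * hill(cifn, p$K1))) +
    p$gamma * hill(cc[4], p$K2) * x[6] - p$delta * x[6]
  dx7 <- (p$beta + p$gamma * hill(cc[3], p$K2) * x[7]) * (1 - x[7] / p$omega) -
    p$delta * x[7]
  dx8 <- p$mu1 * (x[3] + x[5] + x[6]) - p$nu1 * x[8]
  # immune-complex production: damage drives an Erlang chain R[mu2, n]; the
  # chain output (plus any acute inflammatory forcing) is converted at rate
  # mu2.  Under the WT genotype mu2 = 0 and x9 stays at zero.
  dy <- p$mu2 * (c(x[8], y[-n]) - y)
  dx9 <- p$mu2 * (x_on + y[n]) - p$nu2 * x[9]
  dc1 <- p$q * x[3] - p$lambda * hill(cc[1], p$K2) * x[4] - p$eta * cc[1]
  dc2 <- p$q * x[4] - p$lambda * hill(cc[2], p$K2) * x[3] - p$eta * cc[2]
  dc3 <- p$q * x[6] - p$lambda * hill(cc[3], p$K2) * x[7] - p$eta * cc[3]
  dc4 <- p$q * x[7] - p$lambda * hill(cc[4], p$K2) * x[6] - p$eta * cc[4]

  out <- c(dx1, dx2, dx3, dx4, dx5, dx6, dx7, dx8, dx9, dy, dc1, dc2, dc3, dc4)
  names(out) <- state_names(p)
  out
}

#' Initial model state
#'
#' All effector populations, delay-chain intermediates and cytokines start
#' at zero.  The resting tissue-ILC pool `x1` is seeded at a small positive
#' fraction of its carrying capacity and relaxed by a pre-stimulus burn-in
#' of its own logistic dynamics (at baseline interferon `q0`, with every
#' other population held at zero) to the pre-disease steady state, so that
#' reported simulations start from tissue homeostasis rather than from the
#' logistic's degenerate zero fixed point.
#'
#' @param params A [lupus_parameters()] object.
#' @param schedule An [intervention_schedule()].
#' @param seed_fraction Initial `x1` seed as a fraction of `omega`.
#' @param burn_in_days Length of the burn-in integration.
#' @return Named state vector.
#' @export
initial_state <- function(params, schedule = intervention_schedule(),
                          seed_fraction = 0.05, burn_in_days = 400) {
  p <- effective_parameters(params, schedule)
  if (seed_fraction <= 0) {
    stop("`seed_fraction` must be positive: x1 = 0 is a degenerate fixed point",
         call. = FALSE)
  }
  act0 <- p$alpha * saturating_sum(hill(p$q0, p$K1))
  f <- function(t, y, parms) {
    list(p$gamma * (1 - y / p$omega) * y - act0 * y - p$delta * y)
  }
  out <- deSolve::lsoda(seed_fraction * p$omega, c(0, burn_in_days), f,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  x1 <- out[nrow(out), 2L]
  s <- stats::setNames(numeric(13L + p$n_ic), state_names(p))
  s["x1"] <- x1
  s
}
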