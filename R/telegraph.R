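# Telegraph (dichotomous) process of acute inflammatory events.
#
# The process switches between an off-state and an on-state via two
# reactions: R1 (off -> on), a Poisson process whose rate the model calls
# `k_off` (the rate of LEAVING the off-state -- note this naming, which we
# keep for consistency with the response-time formulation), and R2
# (on -> off), a multi-step response-time reaction R[k_on, n_on] so that
# on-durations are Erlang distributed with mean tau_on = n_on / k_on and
# coefficient of variation 1 / sqrt(n_on).

#' Configuration of the acute inflammatory event process
#'
#' @param tau_on Mean on-duration (days).
#' @param tau_off Mean off-duration (days); the off->on rate is `1/tau_off`.
#' @param cv_on Coefficient of variation of on-durations.  Realised via the
#'   chain shape `n_on = round(1/cv_on^2)`, so admissible CVs are
#'   `1/sqrt(integer)`; other values are rounded to the nearest admissible
#'   shape (with a message when the rounding is material).
#' @param xi Immune-complex production scaling of an active event, in (0,1].
#' @return Object of class `telegraph_config` with fields `k_off` (rate of
#'   leaving the off-state), `k_on`, `n_on`, `xi` and the derived `tau_on`,
#'   `sigma_on`, `tau_off`.
#' @export
telegraph_config <- function(tau_on = 7, tau_off = 35, cv_on = 0.5, xi = 0.13) {
  if (tau_on <= 0 || tau_off <= 0) stop("durations must be positive", call. = FALSE)
  if (cv_on <= 0 || cv_on > 1) stop("`cv_on` must be in (0, 1]", call. = FALSE)
  if (xi <= 0 || xi > 1) stop("`xi` must be in (0, 1]", call. = FALSE)
  n_on <- max(1L, as.integer(round(1 / cv_on^2)))
  realised <- 1 / sqrt(n_on)
  if (abs(realised - cv_on) > 1e-8) {
    message(sprintf("cv_on %.3g rounded to 1/sqrt(%d) = %.3g", cv_on, n_on, realised))
  }
  k_on <- n_on / tau_on
  structure(list(k_off = 1 / tau_off, k_on = k_on, n_on = n_on, xi = xi,
                 tau_on = tau_on, sigma_on = sqrt(n_on) / k_on,
                 tau_off = tau_off, cv_on = realised),
            class = "telegraph_config")
}

#' @export
print.telegraph_config <- function(x, ...) {
  cat(sprintf(paste0("telegraph_config: tau_on %.3g d (CV %.3g, n_on %d), ",
                     "tau_off %.3g d, xi %.3g\n"),
              x$tau_on, x$cv_on, x$n_on, x$tau_off, x$xi))
  invisible(x)
}

#' Sample a telegraph path by the stochastic simulation algorithm
#'
#' Exact simulation: starting in the off-state, off-durations are drawn
#' `Exponential(k_off)` and on-durations `Erlang(k_on, n_on)` (a sum of
#' `n_on` exponentials, equivalent to simulating the response-time chain
#' reaction by reaction).
#'
#' @param config A [telegraph_config()].
#' @param horizon Path length in weeks (the path starts at week 0 of the
#'   simulation clock; callers align it with the simulation start).
#' @param seed Optional integer seed for reproducibility.
#' @return Object of class `telegraph_path`: data frame with `time_weeks`
#'   (switch times, strictly increasing, starting at 0) and `state` (0/1,
#'   value from that time until the next switch).
#' @export
sample_telegraph <- function(config, horizon, seed = NULL) {
  stopifnot(inherits(config, "telegraph_config"), horizon > 0)
  if (!is.null(seed)) set.seed(seed)
  horizon_days <- horizon * DAYS_PER_WEEK
  t <- 0
  times <- 0
  states <- 0L
  state <- 0L
  while (t < horizon_days) {
    dt <- if (state == 0L) {
      stats::rexp(1L, rate = config$k_off)
    } else {
      sum(stats::rexp(config$n_on, rate = config$k_on))
    }
    t <- t + dt
    if (t >= horizon_days) break
    state <- 1L - state
    times <- c(times, t)
    states <- c(states, state)
  }
  structure(data.frame(time_weeks = times / DAYS_PER_WEEK, state = states),
            class = c("telegraph_path", "data.frame"),
            horizon = horizon, config = config)
}

#' On/off state of a path at given times
#' @param path A `telegraph_path`.
#' @param t_weeks Query times (weeks).
#' @return Integer vector of 0/1 states.
#' @export
telegraph_state_at <- function(path, t_weeks) {
  idx <- findInterval(t_weeks, path$time_weeks)
  ifelse(idx == 0L, 0L, path$state[pmax(idx, 1L)])
}

#' Total on-time fraction of a path
#' @param path A `telegraph_path`.
#' @export
telegraph_on_fraction <- function(path) {
  horizon <- attr(path, "horizon")
  edges <- c(path$time_weeks, horizon)
  sum(diff(edges)[path$state == 1L]) / horizon
}

#' Write a telegraph path as a two-column CSV
#' @param path A `telegraph_path`.
#' @param file Output file.
#' @export
write_telegraph_path <- function(path, file) {
  utils::write.csv(as.data.frame(path), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Simulate the hybrid stochastic-deterministic model
#'
#' Piecewise-deterministic integration: a telegraph path of acute
#' inflammatory events is sampled (or supplied), and between its switching
#' times the ODE system is integrated with the immune-complex equation
#' `dx9/dt = mu2 * (xi * X_on + y_n) - nu2 * x9`, where `y_n` is the output
#' of the damage-driven delay chain.  The state is continuous across
#' switches; the adaptive solver is restarted at each switch so the
#' discontinuous forcing is never smoothed over.
#'
#' @param params A [lupus_parameters()] object.
#' @param schedule An [intervention_schedule()]; the untreated NZB/W
#'   scenario (`polyic_window = NULL`) is the study condition of interest,
#'   but any schedule is allowed.
#' @param config A [telegraph_config()].
#' @param seed Integer seed (used for path sampling when `path` is `NULL`).
#' @param horizon,start,dt,stop_at_esrd,rtol,atol As in [simulate_lupus()].
#' @param path Optional pre-sampled `telegraph_path` (its clock starts at
#'   `start`).
#' @return A `lupus_trajectory` with the sampled path in attribute
#'   `telegraph_path`.
#' @export
simulate_hybrid <- function(params, schedule = intervention_schedule(polyic_window = NULL),
                            config = telegraph_config(), seed = NULL,
                            horizon = 60, start = 12, dt = 0.1,
                            stop_at_esrd = NULL, rtol = 1e-8, atol = 1e-10,
                            path = NULL) {
  p <- effective_parameters(params, schedule)
  if (is.null(path)) {
    path <- sample_telegraph(config, horizon = horizon - start, seed = seed)
  }
  state <- initial_state(params, schedule)
  t0 <- start * DAYS_PER_WEEK
  t1 <- horizon * DAYS_PER_WEEK
  grid <- seq(t0, t1, by = dt * DAYS_PER_WEEK)
  esrd_value <- if (is.null(stop_at_esrd)) Inf else stop_at_esrd
  sw <- t0 + path$time_weeks * DAYS_PER_WEEK
  st <- path$state
  bounds <- sort(unique(c(sw[sw > t0 & sw < t1], t1)))
  out <- NULL
  a <- t0
  stopped <- FALSE
  for (i in seq_along(bounds)) {
    b <- bounds[i]
    xon <- config$xi * st[findInterval(a + 1e-9, sw)]
    parms <- pack_parms(p, schedule, x_on = xon, esrd_value = esrd_value)
    seg <- integrate_segments(state, a, b, parms, grid, rtol, atol,
                              root = is.finite(esrd_value),
                              segments = segment_breaks(schedule, a, b))
    state <- seg[nrow(seg), -1L]
    out <- rbind(out, if (is.null(out)) seg else seg[-1L, , drop = FALSE])
    if (!is.null(attr(seg, "troot"))) {
      attr(out, "troot") <- attr(seg, "troot")
      stopped <- TRUE
      break
    }
    a <- b
  }
  tr <- as_lupus_trajectory(out, p, schedule)
  attr(tr, "telegraph_path") <- path
  tr
}
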