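# In-silico experiment suite: feedback knockouts, local sensitivity,
# depletion therapy scans.  All scans return tidy data frames ("ScanResult"
# records): one row per grid point per outcome, with censoring flags.

#' Feedback-loop elimination scan
#'
#' Simulates the model with each requested subset of feedback loops
#' eliminated and reports damage at a fixed evaluation week.
#'
#' @param params A [lupus_parameters()] object (typically the `"uniform"`
#'   preset, where all five loops carry equal weight).
#' @param schedule An [intervention_schedule()].
#' @param knockout_sets List of character vectors, each a subset of
#'   `c("F1",...,"F5")`; the empty set is the intact model.
#' @param t_eval Evaluation week for the damage readout.
#' @param horizon Simulation horizon, weeks.
#' @return Data frame with columns `knockouts`, `damage`.
#' @export
feedback_knockout_scan <- function(params, schedule = intervention_schedule(),
                                   knockout_sets = as.list(paste0("F", 1:5)),
                                   t_eval = 25, horizon = 30) {
  rows <- lapply(knockout_sets, function(ko) {
    p <- apply_feedback_knockout(params, ko)
    tr <- simulate_lupus(p, schedule, horizon = horizon)
    data.frame(knockouts = paste(sort(ko), collapse = "+"),
               damage = stats::approx(tr$time_weeks, tr$x8, xout = t_eval)$y)
  })
  do.call(rbind, rows)
}

#' Local sensitivity analysis
#'
#' Varies one scalar parameter at a time by a fixed fraction up and down
#' (all others at default) and records the time to ESRD against the default
#' reference.  Censored outcomes (ESRD never reached within the horizon)
#' are reported with `censored = TRUE`.
#'
#' @param params Baseline [lupus_parameters()].
#' @param schedule An [intervention_schedule()].
#' @param fraction Relative perturbation (default 0.2, i.e. +/-20%).
#' @param ref An [esrd_reference()]; computed from `params` if missing.
#' @param parameters Which parameters to scan; defaults to all positive
#'   scalar rates and weights (structural integers and levels with value 0
#'   are skipped).
#' @param horizon Simulation horizon, weeks.
#' @return Data frame with `parameter`, `direction`, `factor`,
#'   `esrd_week`, `censored`.
#' @export
sensitivity_scan <- function(params, schedule = intervention_schedule(),
                             fraction = 0.2, ref = NULL,
                             parameters = NULL, horizon = 60) {
  stopifnot(fraction >= 0, fraction < 1)
  if (is.null(ref)) ref <- esrd_reference(params)
  if (is.null(parameters)) {
    skip <- "n_ic"
    parameters <- setdiff(.param_names, skip)
    parameters <- parameters[vapply(parameters,
                                    function(nm) params[[nm]] > 0, logical(1))]
  }
  rows <- list()
  for (nm in parameters) {
    for (fac in c(1 + fraction, 1 - fraction)) {
      p <- params
      p[[nm]] <- params[[nm]] * fac
      tr <- simulate_lupus(p, schedule, horizon = horizon,
                           stop_at_esrd = ref$esrd_value)
      tt <- time_to_esrd(tr, ref)
      rows[[length(rows) + 1L]] <-
        data.frame(parameter = nm,
                   direction = if (fac >= 1) "up" else "down",
                   factor = fac, esrd_week = tt$week, censored = tt$censored)
    }
  }
  do.call(rbind, rows)
}

#' Depletion therapy scans
#'
#' Explores timed depletion of tissue ILC and/or vessel NK cells.  Two scan
#' modes: a strength scan at the default window, and an onset-by-duration
#' grid at the default strength.
#'
#' @param params A [lupus_parameters()] object.
#' @param schedule Base schedule (genotype, poly(I:C) window); depletion
#'   fields are overridden by the scan.
#' @param targets List of character vectors naming the depletion modes to
#'   scan, e.g. `list("tILC", "vNK", c("tILC","vNK"))`.
#' @param strengths Numeric vector of depletion strengths for the strength
#'   scan, or `NULL` to skip.
#' @param onsets,durations Numeric vectors (weeks) spanning the
#'   onset-by-duration grid, or `NULL` to skip.
#' @param ref An [esrd_reference()]; computed from `params` if missing.
#' @param horizon Simulation horizon, weeks.
#' @return Data frame with `mode`, `strength`, `onset`, `duration`,
#'   `esrd_week`, `censored`.
#' @export
depletion_scan <- function(params, schedule = intervention_schedule(),
                           targets = list("tILC", "vNK", c("tILC", "vNK")),
                           strengths = NULL, onsets = NULL, durations = NULL,
                           ref = NULL, horizon = 60) {
  if (is.null(ref)) ref <- esrd_reference(params)
  run1 <- function(tg, strength, window) {
    sch <- intervention_schedule(genotype = schedule$genotype,
                                 polyic_window = schedule$polyic_window,
                                 depletion_targets = tg,
                                 depletion_strength = strength,
                                 depletion_window = window,
                                 feedback_knockouts = schedule$feedback_knockouts)
    tr <- simulate_lupus(params, sch, horizon = horizon,
                         stop_at_esrd = ref$esrd_value)
    time_to_esrd(tr, ref)
  }
  rows <- list()
  for (tg in targets) {
    mode <- paste(sort(tg), collapse = "+")
    if (!is.null(strengths)) {
      for (s in strengths) {
        tt <- if (s == 0) {
          run1(character(), 0.5, schedule$depletion_window %||% c(19, 25))
        } else {
          run1(tg, s, schedule$depletion_window %||% c(19, 25))
        }
        rows[[length(rows) + 1L]] <-
          data.frame(mode = mode, strength = s, onset = NA_real_,
                     duration = NA_real_, esrd_week = tt$week,
                     censored = tt$censored)
      }
    }
    if (!is.null(onsets) && !is.null(durations)) {
      for (on in onsets) for (du in durations) {
        tt <- run1(tg, schedule$depletion_strength, c(on, on + du))
        rows[[length(rows) + 1L]] <-
          data.frame(mode = mode, strength = schedule$depletion_strength,
                     onset = on, duration = du, esrd_week = tt$week,
                     censored = tt$censored)
      }
    }
  }
  do.call(rbind, rows)
}
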