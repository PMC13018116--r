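# Outcome normalisation: end-stage renal disease (ESRD) reference and
# derived outcomes.  ESRD is defined as reaching 95% of the maximal damage
# of the default NZB/W + poly(I:C) deterministic run; pre-ESRD (the model's
# proteinuria proxy) is 70% of the ESRD damage value, evaluated at week 25.

#' ESRD reference of a parameter set
#'
#' Runs the default NZB/W + poly(I:C) deterministic simulation over a fixed
#' long horizon, takes 95% of its maximal damage as the ESRD damage value,
#' the first crossing of that value as the reference ESRD time, and 70% of
#' the ESRD value as the pre-ESRD threshold.
#'
#' @param params A [lupus_parameters()] object.
#' @param schedule The reference schedule; defaults to NZB/W + poly(I:C)
#'   weeks 19-23, no depletion.
#' @param horizon Reference horizon in weeks.
#' @return Object of class `esrd_reference` with `esrd_value`,
#'   `pre_esrd_value`, `esrd_week`, `max_damage`.
#' @export
esrd_reference <- function(params, schedule = intervention_schedule(),
                           horizon = 60) {
  tr <- simulate_lupus(params, schedule, horizon = horizon)
  M <- max(tr$x8)
  esrd_value <- 0.95 * M
  wk <- crossing_week(tr, esrd_value)
  if (is.na(wk)) {
    stop("damage never reaches 95% of its maximum before the end of the ",
         "reference run: mis-calibrated parameters", call. = FALSE)
  }
  structure(list(esrd_value = esrd_value, pre_esrd_value = 0.7 * esrd_value,
                 esrd_week = wk, max_damage = M, horizon = horizon),
            class = "esrd_reference")
}

#' @export
print.esrd_reference <- function(x, ...) {
  cat(sprintf(paste0("esrd_reference: ESRD damage %.4g (95%% of max %.4g), ",
                     "reached week %.2f; pre-ESRD %.4g\n"),
              x$esrd_value, x$max_damage, x$esrd_week, x$pre_esrd_value))
  invisible(x)
}

# First crossing of a damage threshold, linearly interpolated between
# output grid points.  NA if never crossed.
crossing_week <- function(trajectory, value) {
  x8 <- trajectory$x8
  wk <- trajectory$time_weeks
  i <- which(x8 >= value)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(wk[1])
  wk[i - 1L] + (value - x8[i - 1L]) / (x8[i] - x8[i - 1L]) * (wk[i] - wk[i - 1L])
}

#' Time to ESRD of a trajectory
#'
#' @param trajectory A `lupus_trajectory`.
#' @param ref An [esrd_reference()].
#' @return List with `week` (first crossing of the ESRD damage value, by
#'   linear interpolation on the output grid) and `censored` (`TRUE` when
#'   the trajectory never crosses within its horizon, in which case `week`
#'   is `NA`).
#' @export
time_to_esrd <- function(trajectory, ref) {
  stopifnot(inherits(ref, "esrd_reference"))
  wk <- crossing_week(trajectory, ref$esrd_value)
  list(week = wk, censored = is.na(wk))
}

#' Pre-ESRD classification at a fixed evaluation time
#'
#' `TRUE` when the trajectory has reached the pre-ESRD damage value (70% of
#' the ESRD damage value) by `t_eval` weeks; the model's analogue of a
#' positive proteinuria measurement at 25 weeks of age.  Like proteinuria
#' onset in the animal experiments, this is a cumulative event: a run that
#' crossed the threshold during the stimulation window counts even if its
#' damage is transiently lower at `t_eval` itself.  Set `cumulative =
#' FALSE` to classify on the instantaneous damage at `t_eval` instead.
#'
#' @param trajectory A `lupus_trajectory` covering `t_eval`.
#' @param ref An [esrd_reference()].
#' @param t_eval Evaluation time, weeks (default 25).
#' @param cumulative Classify on the running damage maximum (default) or
#'   on the instantaneous value.
#' @export
pre_esrd_at <- function(trajectory, ref, t_eval = 25, cumulative = TRUE) {
  stopifnot(inherits(ref, "esrd_reference"))
  if (t_eval < min(trajectory$time_weeks) - 1e-9 ||
      t_eval > max(trajectory$time_weeks) + 1e-9) {
    stop(sprintf("t_eval = %g weeks is outside the trajectory", t_eval),
         call. = FALSE)
  }
  x8 <- stats::approx(trajectory$time_weeks, trajectory$x8, xout = t_eval,
                      rule = 2)$y
  if (cumulative) {
    x8 <- max(x8, trajectory$x8[trajectory$time_weeks <= t_eval])
  }
  x8 >= ref$pre_esrd_value
}

#' Stochastic onset delay of a hybrid run
#'
#' `t_stoch` is the time to ESRD of a hybrid-model trajectory minus the
#' reference ESRD time of the deterministic poly(I:C)-treated model.
#'
#' @param trajectory A hybrid `lupus_trajectory`.
#' @param ref An [esrd_reference()] (its `esrd_week` is the subtrahend).
#' @return List with `weeks` (the delay; `NA` when censored) and
#'   `censored`.
#' @export
t_stoch <- function(trajectory, ref) {
  tt <- time_to_esrd(trajectory, ref)
  list(weeks = if (tt$censored) NA_real_ else tt$week - ref$esrd_week,
       censored = tt$censored)
}
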