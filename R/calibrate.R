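# Calibration of the free parameters.
#
# The literature-anchored kinetic rates are fixed; the remaining constants
# are pinned by ordered behavioural constraints on the model's study
# conditions rather than by direct measurements.  `calibrate_defaults()`
# implements that procedure as a seeded local search; the shipped preset in
# `lupus_parameters()` is its output and satisfies the constraint set.

#' Local maxima of the interferon trace
#'
#' Peaks of the algebraic interferon concentration along a trajectory.
#' Plateaus count once (at their first time point), and a trace that is
#' still rising when the simulation stops (the convention when integration
#' halts at the damage threshold) contributes its end point.
#'
#' @param trajectory A `lupus_trajectory`.
#' @param min_prominence Minimum rise above the preceding minimum for a
#'   peak to count.
#' @return Data frame with `week` and `value`, in time order.
#' @export
ifn_peaks <- function(trajectory, min_prominence = 0.02) {
  w <- trajectory$time_weeks
  v <- trajectory$c
  n <- length(v)
  peaks <- list()
  last_min <- v[1]
  i <- 2L
  while (i <= n) {
    if (v[i] < v[i - 1L] - 1e-12) {
      # find start of the preceding plateau/maximum
      j <- i - 1L
      while (j > 1L && abs(v[j - 1L] - v[j]) <= 1e-12) j <- j - 1L
      if (v[i - 1L] - last_min >= min_prominence) {
        peaks[[length(peaks) + 1L]] <- c(w[j], v[j])
      }
      # descend to the next local minimum
      while (i <= n && v[i] <= v[i - 1L] + 1e-12) i <- i + 1L
      last_min <- v[i - 1L]
    } else i <- i + 1L
  }
  # a trace that ends rising, or ends on a plateau it rose onto (e.g. the
  # feedback term saturating the interferon cap before an ESRD stop),
  # contributes the first point of that terminal maximum
  j <- n
  while (j > 1L && abs(v[j - 1L] - v[j]) <= 1e-12) j <- j - 1L
  if (j > 1L && v[n] > v[j - 1L] + 1e-12 && v[n] - last_min >= min_prominence) {
    peaks[[length(peaks) + 1L]] <- c(w[j], v[j])
  }
  out <- do.call(rbind, peaks)
  if (is.null(out)) {
    return(data.frame(week = numeric(), value = numeric()))
  }
  data.frame(week = out[, 1], value = out[, 2])
}

#' Shipped calibration constraint set
#'
#' The ordered constraints that pin the free parameters:
#' two-peak interferon response under NZB/W + poly(I:C) with the first peak
#' inside the stimulation window and the second inside the given late
#' window; wild-type recovery (damage at week 35 below a fraction of its
#' peak); a fixed interval between reaching the pre-ESRD and ESRD damage
#' values in the untreated deterministic model; virtual-cohort pre-ESRD
#' fractions for the treated and tILC-depleted scenarios; a hybrid-model
#' pre-ESRD fraction; and the fixed down-scaled immune-complex feedback
#' weights `zeta3 = zeta5 = 0.2`.
#'
#' @param cohort_n Cohort size used when evaluating the fraction
#'   constraints during calibration (the full study size of 1000 is used by
#'   the reporting scripts; a smaller default keeps the search affordable).
#' @return Named list of constraint settings.
#' @export
calibration_constraints <- function(cohort_n = 150) {
  list(first_peak_window = c(19, 23),
       second_peak_window = c(25, 27),
       wt_recovery_fraction = 0.10,
       untreated_gap_weeks = 7.6, untreated_gap_tol = 1,
       cohort_treated_fraction = 0.92,
       cohort_depleted_fraction = 0.26,
       cohort_tol = 0.10,
       hybrid_fraction = 0.15, hybrid_tol = 0.07,
       zeta_ic = 0.2,
       cohort_n = cohort_n)
}

#' Evaluate the calibration constraints for a parameter set
#'
#' @param params A [lupus_parameters()] object.
#' @param constraints See [calibration_constraints()].
#' @param config Telegraph configuration for the hybrid constraint.
#' @param seed Seed for the cohort/hybrid evaluations.
#' @param deterministic_only Skip the (expensive) cohort and hybrid
#'   fraction constraints.
#' @return List with `ok` (named logicals), `values` (named numerics) and
#'   `score` (total weighted violation; 0 when all constraints hold).
#' @export
check_calibration <- function(params, constraints = calibration_constraints(),
                              config = telegraph_config(), seed = 1,
                              deterministic_only = FALSE) {
  cs <- constraints
  vals <- c()
  ok <- c()
  viol <- 0
  add <- function(name, value, pass, excess) {
    vals[[name]] <<- value
    ok[[name]] <<- pass
    viol <<- viol + excess
  }

  # interferon peak structure (treated run, stopped at the damage threshold)
  ref <- tryCatch(esrd_reference(params), error = function(e) NULL)
  if (is.null(ref)) {
    return(list(ok = c(reference = FALSE), values = c(),
                score = Inf))
  }
  tr <- simulate_lupus(params, intervention_schedule(),
                       horizon = ref$horizon, stop_at_esrd = ref$esrd_value)
  pk <- ifn_peaks(tr)
  in_win <- function(x, w) !is.na(x) && x >= w[1] && x <= w[2]
  p1 <- if (nrow(pk) >= 1) pk$week[1] else NA_real_
  p2 <- if (nrow(pk) >= 2) pk$week[2] else NA_real_
  add("two_peaks", nrow(pk), nrow(pk) == 2,
      if (nrow(pk) == 2) 0 else 2 * abs(nrow(pk) - 2))
  add("first_peak_week", p1, in_win(p1, cs$first_peak_window),
      if (is.na(p1)) 4 else max(0, cs$first_peak_window[1] - p1, p1 - cs$first_peak_window[2]))
  add("second_peak_week", p2, in_win(p2, cs$second_peak_window),
      if (is.na(p2)) 4 else max(0, cs$second_peak_window[1] - p2, p2 - cs$second_peak_window[2]))

  # wild-type recovery
  wt <- simulate_lupus(params, intervention_schedule(genotype = "WT"),
                       horizon = 36)
  rec <- stats::approx(wt$time_weeks, wt$x8, xout = 35)$y / max(wt$x8)
  add("wt_recovery", rec, rec < cs$wt_recovery_fraction,
      10 * max(0, rec - cs$wt_recovery_fraction))

  # untreated pre-ESRD to ESRD interval
  un <- simulate_lupus(params, intervention_schedule(polyic_window = NULL),
                       horizon = 70)
  tE <- crossing_week(un, ref$esrd_value)
  tP <- crossing_week(un, ref$pre_esrd_value)
  gap <- tE - tP
  add("untreated_gap", gap,
      !is.na(gap) && abs(gap - cs$untreated_gap_weeks) <= cs$untreated_gap_tol,
      if (is.na(gap)) 8 else max(0, abs(gap - cs$untreated_gap_weeks) - cs$untreated_gap_tol))

  # fixed immune-complex feedback weights
  add("zeta_ic", params$zeta3,
      params$zeta3 == cs$zeta_ic && params$zeta5 == cs$zeta_ic,
      (params$zeta3 != cs$zeta_ic) + (params$zeta5 != cs$zeta_ic))

  if (!deterministic_only) {
    n <- cs$cohort_n
    f_tr <- cohort_pre_esrd_fraction(params, intervention_schedule(),
                                     n = n, seed = seed)$fraction
    add("cohort_treated", f_tr,
        abs(f_tr - cs$cohort_treated_fraction) <= cs$cohort_tol,
        5 * max(0, abs(f_tr - cs$cohort_treated_fraction) - cs$cohort_tol))
    f_dep <- cohort_pre_esrd_fraction(
      params, intervention_schedule(depletion_targets = "tILC"),
      n = n, seed = seed)$fraction
    add("cohort_depleted", f_dep,
        abs(f_dep - cs$cohort_depleted_fraction) <= cs$cohort_tol,
        5 * max(0, abs(f_dep - cs$cohort_depleted_fraction) - cs$cohort_tol))
    f_hy <- hybrid_pre_esrd_fraction(params, config, n = n,
                                     seed = seed)$fraction
    add("hybrid", f_hy, abs(f_hy - cs$hybrid_fraction) <= cs$hybrid_tol,
        5 * max(0, abs(f_hy - cs$hybrid_fraction) - cs$hybrid_tol))
  }
  list(ok = ok, values = vals, score = viol)
}

# Free parameters explored by the calibration search.  mu1 (damage
# acquisition, fixed to the six-week timescale), omega (the intrinsic
# unit), the chain shape and the held zeta3/zeta5 are not searched.
.calibration_free <- c("K1", "K2", "K3", "zeta1", "zeta2", "zeta4",
                       "vartheta", "nu1", "mu2", "nu2", "q0", "q1", "q2")

#' Calibrate the free parameters
#'
#' Seeded local search over the free parameters minimising the violation of
#' the constraint set: candidate sets are drawn log-uniformly around the
#' starting point and scored with [check_calibration()]; the best-scoring
#' candidate is returned together with the search log.  With the shipped
#' starting point (the packaged preset) and constraints the start already
#' satisfies every deterministic constraint and the search returns it
#' unchanged, which keeps the procedure cheap and reproducible; the same
#' routine with a perturbed start documents how the preset was found.
#'
#' @param start Starting [lupus_parameters()].
#' @param constraints See [calibration_constraints()].
#' @param n_candidates Number of perturbed candidates to score (in addition
#'   to the start).
#' @param spread Log-scale half-width of the candidate perturbations.
#' @param seed Integer seed; the search is deterministic given the seed.
#' @param deterministic_only Calibrate against the deterministic
#'   constraints only (default; the fraction constraints are expensive and
#'   are verified separately by the reporting scripts).
#' @return List with `params` (class `lupus_parameters`), `check` (the
#'   constraint evaluation of the returned preset) and `log` (one row per
#'   scored candidate).
#' @export
calibrate_defaults <- function(start = lupus_parameters(),
                               constraints = calibration_constraints(),
                               n_candidates = 20, spread = 0.1, seed = 1,
                               deterministic_only = TRUE) {
  set.seed(seed)
  score1 <- function(p) {
    chk <- tryCatch(
      check_calibration(p, constraints, seed = seed,
                        deterministic_only = deterministic_only),
      error = function(e) list(ok = c(error = FALSE), values = c(), score = Inf))
    chk
  }
  best <- start
  best_chk <- score1(start)
  log <- data.frame(candidate = 0L, score = best_chk$score)
  if (best_chk$score > 0 && n_candidates > 0) {
    for (i in seq_len(n_candidates)) {
      cand <- start
      for (nm in .calibration_free) {
        cand[[nm]] <- start[[nm]] * exp(stats::runif(1, -spread, spread))
      }
      cand$zeta3 <- constraints$zeta_ic
      cand$zeta5 <- constraints$zeta_ic
      chk <- score1(cand)
      log <- rbind(log, data.frame(candidate = i, score = chk$score))
      if (chk$score < best_chk$score) {
        best <- cand
        best_chk <- chk
      }
      if (best_chk$score == 0) break
    }
  }
  list(params = best, check = best_chk, log = log)
}
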