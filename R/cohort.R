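# Virtual cohorts: robustness analysis with multiplicative log-normal
# parameter variation, and hybrid-model onset statistics.
#
# Seeding convention: one flat seed per cohort; member i uses substream
# seed + i for its parameter draw and (for hybrid runs) seed + 500000 + i
# for its telegraph path, so that enlarging the cohort never perturbs
# earlier members.

#' Parameters perturbed in cohort sampling
#'
#' All positive scalar rate/weight/level parameters; structural integers
#' (the chain shape) and parameters fixed at zero (e.g. `mu2` under WT) are
#' left untouched.
#'
#' @param params A [lupus_parameters()] object.
#' @export
cohort_varied_parameters <- function(params) {
  nm <- setdiff(.param_names, "n_ic")
  nm[vapply(nm, function(n) params[[n]] > 0, logical(1))]
}

#' Draw one cohort member's parameter set
#'
#' Each varied parameter is multiplied by `exp(rnorm(1, 0, sd_log))`:
#' multiplicative log-normal noise centred (in log space) on the default,
#' giving a coefficient of variation of about `sd_log`.
#'
#' @param params Baseline [lupus_parameters()].
#' @param sd_log Log-scale standard deviation (default 0.1, ~10% CV).
#' @param seed Integer seed for this draw.
#' @return Perturbed `lupus_parameters`.
#' @export
sample_cohort_parameters <- function(params, sd_log = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- cohort_varied_parameters(params)
  eps <- stats::rnorm(length(nm), mean = 0, sd = sd_log)
  for (i in seq_along(nm)) params[[nm[i]]] <- params[[nm[i]]] * exp(eps[i])
  params
}

#' Cohort pre-ESRD fraction
#'
#' Simulates `n` cohort members under a scenario, classifying each by
#' whether damage at `t_eval` weeks reaches the pre-ESRD threshold of the
#' fixed reference, and returns the positive fraction with its binomial
#' standard error.
#'
#' @param params Baseline [lupus_parameters()].
#' Model kinetics are normalised per parameter set: each member is
#' classified against the ESRD reference computed from its *own* sampled
#' parameters (the member's default treated run), so the comparison asks
#' whether that virtual animal's disease course reaches its pre-ESRD level
#' by `t_eval`, not whether its absolute damage scale exceeds the baseline
#' animal's.
#'
#' @param schedule Scenario [intervention_schedule()].
#' @param n Cohort size.
#' @param sd_log Log-scale parameter noise (0 gives a degenerate cohort).
#' @param seed Flat cohort seed.
#' @param ref Optional fixed [esrd_reference()]; by default each member is
#'   normalised against its own reference (`ref = NULL`).
#' @param t_eval Classification week (default 25).
#' @return List with `fraction`, `se`, `n`, and the per-member logical
#'   vector `pre_esrd`.
#' @export
cohort_pre_esrd_fraction <- function(params, schedule = intervention_schedule(),
                                     n = 1000, sd_log = 0.1, seed = 1,
                                     ref = NULL, t_eval = 25) {
  stopifnot(n >= 1)
  hits <- logical(n)
  for (i in seq_len(n)) {
    p_i <- sample_cohort_parameters(params, sd_log = sd_log, seed = seed + i)
    ref_i <- if (is.null(ref)) esrd_reference(p_i) else ref
    tr <- simulate_lupus(p_i, schedule, horizon = t_eval + 1)
    hits[i] <- pre_esrd_at(tr, ref_i, t_eval = t_eval)
  }
  frac <- mean(hits)
  list(fraction = frac, se = sqrt(frac * (1 - frac) / n), n = n,
       pre_esrd = hits)
}

#' Hybrid-model pre-ESRD fraction
#'
#' `n` hybrid runs of the untreated NZB/W scenario, each with an
#' independent parameter draw and an independent seeded telegraph path;
#' returns the fraction reaching pre-ESRD at `t_eval` weeks.
#'
#' @param params Baseline [lupus_parameters()].
#' @param config A [telegraph_config()].
#' @param schedule Scenario; defaults to untreated NZB/W.
#' Members are normalised per parameter set as in
#' [cohort_pre_esrd_fraction()].
#'
#' @param n,sd_log,seed,ref,t_eval As in [cohort_pre_esrd_fraction()].
#' @return List with `fraction`, `se`, `n`, `pre_esrd`.
#' @export
hybrid_pre_esrd_fraction <- function(params, config = telegraph_config(),
                                     schedule = intervention_schedule(polyic_window = NULL),
                                     n = 1000, sd_log = 0.1, seed = 1,
                                     ref = NULL, t_eval = 25) {
  stopifnot(n >= 1)
  hits <- logical(n)
  for (i in seq_len(n)) {
    p_i <- sample_cohort_parameters(params, sd_log = sd_log, seed = seed + i)
    ref_i <- if (is.null(ref)) esrd_reference(p_i) else ref
    tr <- simulate_hybrid(p_i, schedule, config, seed = seed + 500000L + i,
                          horizon = t_eval + 1)
    hits[i] <- pre_esrd_at(tr, ref_i, t_eval = t_eval)
  }
  frac <- mean(hits)
  list(fraction = frac, se = sqrt(frac * (1 - frac) / n), n = n,
       pre_esrd = hits)
}

#' Stochastic-resonance scan over the switching frequency
#'
#' Varies the switching frequency of the inflammatory-event process while
#' holding the total expected on-fraction and the on-duration CV constant,
#' and summarises the stochastic onset delay `t_stoch` at each grid point.
#' A frequency factor `f` rescales both `tau_on` and `tau_off` by `1/f`.
#'
#' @param params Baseline [lupus_parameters()].
#' @param config Base [telegraph_config()] (defines on-fraction and CV).
#' @param freq_factors Positive multipliers of the base switching
#'   frequency.
#' @param n Hybrid runs per grid point.
#' @param seed Flat seed.
#' @param ref An [esrd_reference()]; computed if missing.
#' @param horizon Simulation horizon, weeks.
#' @param sd_log Parameter noise of the runs (0 isolates event noise).
#' @return Data frame with `freq_factor`, `mean_t_stoch`, `sd_t_stoch`,
#'   `n_censored`, `n`.
#' @export
resonance_scan <- function(params, config = telegraph_config(),
                           freq_factors = c(0.25, 0.5, 1, 2, 4),
                           n = 50, seed = 1, ref = NULL, horizon = 80,
                           sd_log = 0) {
  stopifnot(length(freq_factors) >= 1, all(freq_factors > 0))
  if (is.null(ref)) ref <- esrd_reference(params)
  schedule <- intervention_schedule(polyic_window = NULL)
  rows <- lapply(seq_along(freq_factors), function(k) {
    f <- freq_factors[k]
    cfg <- telegraph_config(tau_on = config$tau_on / f,
                            tau_off = config$tau_off / f,
                            cv_on = config$cv_on, xi = config$xi)
    ts <- numeric(n)
    cens <- logical(n)
    for (i in seq_len(n)) {
      p_i <- if (sd_log > 0) {
        sample_cohort_parameters(params, sd_log, seed = seed + i)
      } else params
      tr <- simulate_hybrid(p_i, schedule, cfg,
                            seed = seed + 1000000L * k + i,
                            horizon = horizon, stop_at_esrd = ref$esrd_value)
      r <- t_stoch(tr, ref)
      ts[i] <- r$weeks
      cens[i] <- r$censored
    }
    ok <- !cens
    data.frame(freq_factor = f,
               mean_t_stoch = if (any(ok)) mean(ts[ok]) else NA_real_,
               sd_t_stoch = if (sum(ok) > 1) stats::sd(ts[ok]) else NA_real_,
               n_censored = sum(cens), n = n)
  })
  do.call(rbind, rows)
}
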