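#' Intervention schedule for a simulation scenario
#'
#' Time-windowed external controls applied to a model run: the poly(I:C)
#' stimulation window, a depletion treatment (which compartments, how
#' strongly, when), and feedback-loop knockouts.  All times are weeks of
#' age.
#'
#' Depletion multiplies the tissue-ILC carrying capacity (target `"tILC"`)
#' and/or the NK-cell migration rate (target `"vNK"`) by `1 - strength`
#' while the window is active: at the default strength 0.8 the affected
#' process runs at 20% of its normal level, emulating antibody-mediated
#' depletion that suppresses the compartment by more than 80%.
#'
#' @param genotype `"NZBW"` or `"WT"`.
#' @param polyic_window Length-2 numeric, weeks of age during which
#'   poly(I:C) drives interferon; `NULL` for an untreated scenario.
#' @param depletion_targets Character subset of `c("tILC", "vNK")`.
#' @param depletion_strength Fraction `kappa` in `[0, 1]`.
#' @param depletion_window Length-2 numeric, weeks.
#' @param feedback_knockouts Character subset of `c("F1",...,"F5")`, applied
#'   to the parameters at simulation time.
#' @return Object of class `intervention_schedule`.
#' @examples
#' intervention_schedule()                       # NZB/W + poly(I:C) weeks 19-23
#' intervention_schedule(polyic_window = NULL)   # untreated
#' @export
intervention_schedule <- function(genotype = c("NZBW", "WT"),
                                  polyic_window = c(19, 23),
                                  depletion_targets = character(),
                                  depletion_strength = 0.8,
                                  depletion_window = c(19, 25),
                                  feedback_knockouts = character()) {
  genotype <- match.arg(genotype)
  chk_window <- function(w, what) {
    if (is.null(w)) return(NULL)
    if (!is.numeric(w) || length(w) != 2L || any(!is.finite(w)) || w[1] >= w[2]) {
      stop(sprintf("`%s` must be an increasing pair of weeks", what), call. = FALSE)
    }
    as.numeric(w)
  }
  polyic_window <- chk_window(polyic_window, "polyic_window")
  depletion_window <- chk_window(depletion_window, "depletion_window")
  bad <- setdiff(depletion_targets, c("tILC", "vNK"))
  if (length(bad)) {
    stop("unknown depletion target(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(depletion_strength) || length(depletion_strength) != 1L ||
      depletion_strength < 0 || depletion_strength > 1) {
    stop("`depletion_strength` must be in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(feedback_knockouts, paste0("F", 1:5))
  if (length(bad)) {
    stop("unknown feedback label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(genotype = genotype,
                 polyic_window = polyic_window,
                 depletion_targets = unique(depletion_targets),
                 depletion_strength = depletion_strength,
                 depletion_window = depletion_window,
                 feedback_knockouts = unique(feedback_knockouts)),
            class = "intervention_schedule")
}

#' @export
print.intervention_schedule <- function(x, ...) {
  fmt_w <- function(w) if (is.null(w)) "none" else sprintf("weeks %g-%g", w[1], w[2])
  cat(sprintf("intervention_schedule: genotype %s\n", x$genotype))
  cat(sprintf("  poly(I:C): %s\n", fmt_w(x$polyic_window)))
  if (length(x$depletion_targets)) {
    cat(sprintf("  depletion: %s, strength %.2f, %s\n",
                paste(x$depletion_targets, collapse = "+"),
                x$depletion_strength, fmt_w(x$depletion_window)))
  } else cat("  depletion: none\n")
  if (length(x$feedback_knockouts)) {
    cat(sprintf("  knockouts: %s\n", paste(x$feedback_knockouts, collapse = ", ")))
  }
  invisible(x)
}

# Effective parameters for a run: genotype switch and knockouts applied.
effective_parameters <- function(params, schedule) {
  stopifnot(inherits(params, "lupus_parameters"),
            inherits(schedule, "intervention_schedule"))
  params <- apply_feedback_knockout(params, schedule$feedback_knockouts)
  if (schedule$genotype == "WT") params$mu2 <- 0
  params
}
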