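# Model parameters for the lupus-nephritis interaction model.
#
# Literature-anchored kinetic rates (per day): maximal proliferation 2.4,
# removal 0.24, maximal infiltration 2.4, activation 4.8, maximal endocytosis
# 14.4, maximal secretion 1.44, cytokine degradation 0.24.  These are fixed
# defaults.  The remaining constants (Hill half-saturations, feedback
# weights, damage and immune-complex kinetics, interferon levels) are free
# parameters fixed by the calibration procedure in `calibrate_defaults()`;
# the shipped values are the calibrated preset.

.table_rates <- c(gamma = 2.4, delta = 0.24, beta = 2.4, alpha = 4.8,
                  lambda = 14.4, q = 1.44, eta = 0.24)

# Calibrated defaults (see calibrate_defaults() and the methods vignette).
# zeta3 = zeta5 = 0.2 down-scale immune-complex driven infiltration of
# tissue macrophages and monocytes, emphasising the ILC-mediated route.
.calibrated_defaults <- list(
  omega = 1,
  K1 = 0.48, K2 = 0.93, K3 = 4.8,
  zeta1 = 3.5, zeta2 = 3.5, zeta3 = 0.2, zeta4 = 3.5, zeta5 = 0.2,
  vartheta = 0.8,
  mu1 = 1 / 42, nu1 = 1.49,
  mu2 = 0.107, nu2 = 0.0079, n_ic = 3L,
  q0 = 0.03, q1 = 0.66, q2 = 1.86
)

# Uniform-feedback variant: all five feedback weights equal, used for the
# feedback-loop elimination analysis on the unmodified topology.
.uniform_zeta <- 3.5

.param_names <- c(names(.table_rates), names(.calibrated_defaults))

#' Parameters of the lupus-nephritis model
#'
#' Returns the full parameter record: fixed kinetic rates (proliferation
#' `gamma`, removal `delta`, infiltration `beta`, activation `alpha`,
#' endocytosis `lambda`, secretion `q`, degradation `eta`, all per day)
#' together with the calibrated free parameters (Hill constants `K1`-`K3`,
#' feedback weights `zeta1`-`zeta5`, interferon-to-monocyte weight
#' `vartheta`, damage kinetics `mu1`, `nu1`, immune-complex kinetics `mu2`,
#' `nu2` and chain shape `n_ic`, and the interferon concentration levels
#' `q0` (baseline), `q1` (poly(I:C) induced), `q2` (feedback induced)).
#'
#' Under the `"WT"` genotype `mu2 = 0`: without autoantibodies there is no
#' damage-driven immune-complex deposition, which inactivates all
#' immune-complex gated feedback.
#'
#' @param genotype `"NZBW"` (lupus-prone, default) or `"WT"`.
#' @param preset `"depletion_scaled"` (shipped default; immune-complex
#'   feedback on macrophage/monocyte infiltration down-weighted to 0.2) or
#'   `"uniform"` (all five feedback weights equal).
#' @param ... Named overrides of individual parameters.
#' @return Object of class `lupus_parameters` (a named list).
#' @examples
#' p <- lupus_parameters()
#' p$gamma   # 2.4 per day
#' @export
lupus_parameters <- function(genotype = c("NZBW", "WT"),
                             preset = c("depletion_scaled", "uniform"), ...) {
  genotype <- match.arg(genotype)
  preset <- match.arg(preset)
  p <- c(as.list(.table_rates), .calibrated_defaults)
  if (preset == "uniform") {
    p[paste0("zeta", 1:5)] <- .uniform_zeta
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), .param_names)
  if (length(unknown)) {
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  p[names(dots)] <- dots
  if (genotype == "WT") p$mu2 <- 0
  p$n_ic <- as.integer(p$n_ic)
  validate_parameters(p)
  structure(p, genotype = genotype, preset = preset, class = "lupus_parameters")
}

#' @rdname lupus_parameters
#' @export
default_parameters <- function(genotype = c("NZBW", "WT")) {
  lupus_parameters(genotype = match.arg(genotype))
}

validate_parameters <- function(p) {
  miss <- setdiff(.param_names, names(p))
  if (length(miss)) stop("missing parameter(s): ", paste(miss, collapse = ", "),
                         call. = FALSE)
  num <- p[setdiff(.param_names, "n_ic")]
  if (!all(vapply(num, function(v) is.numeric(v) && length(v) == 1L && v >= 0,
                  logical(1)))) {
    stop("all rate parameters must be single non-negative numbers", call. = FALSE)
  }
  if (p$n_ic < 1L) stop("`n_ic` must be a positive integer", call. = FALSE)
  for (K in c("K1", "K2", "K3")) {
    if (p[[K]] <= 0) stop(sprintf("`%s` must be > 0", K), call. = FALSE)
  }
  invisible(p)
}

#' @export
print.lupus_parameters <- function(x, ...) {
  cat(sprintf("lupus_parameters (genotype %s, preset %s)\n",
              attr(x, "genotype"), attr(x, "preset")))
  v <- unlist(x[.param_names])
  print(signif(v, 4))
  invisible(x)
}

#' Eliminate feedback loops
#'
#' The five positive feedback loops of the model map onto the weights
#' `zeta1`-`zeta5`: F1 is direct damage-induced interferon release (`zeta1`),
#' F2 damage-induced activation of resting tissue ILC (`zeta2`), F3
#' immune-complex driven macrophage infiltration (`zeta3`), F4
#' immune-complex induced interferon (`zeta4`) and F5 immune-complex driven
#' monocyte infiltration (`zeta5`).  Eliminating F3, F4 and F5 together
#' removes every immune-complex mediated pathway and is equivalent to the
#' wild-type condition.
#'
#' @param params A [lupus_parameters()] object.
#' @param knockouts Character subset of `c("F1","F2","F3","F4","F5")`.
#' @return Modified copy of `params` with the selected weights set to zero.
#' @export
apply_feedback_knockout <- function(params, knockouts = character()) {
  stopifnot(inherits(params, "lupus_parameters"))
  if (length(knockouts) == 0) return(params)
  valid <- paste0("F", 1:5)
  bad <- setdiff(knockouts, valid)
  if (length(bad)) {
    stop("unknown feedback label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (f in knockouts) {
    params[[paste0("zeta", substring(f, 2))]] <- 0
  }
  params
}
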