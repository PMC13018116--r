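#' Cubic Hill gating function
#'
#' Saturating response `x^3 / (K^3 + x^3)` used throughout the framework to
#' gate rates by cell abundances or cytokine concentrations.  The exponent is
#' fixed at 3: all couplings in the model family are cubic, which gives a
#' switch-like but continuous response around the half-saturation constant.
#'
#' @param x Non-negative input level (scalar or vector), intrinsic units.
#' @param K Half-saturation constant, `K > 0`; `hill(K, K)` is exactly 1/2.
#' @return Values in `[0, 1)`, strictly increasing in `x`.
#' @examples
#' hill(0.5, 0.5)      # 0.5
#' hill(1, 0.5)        # 8/9
#' @export
hill <- function(x, K) {
  if (!is.numeric(x) || !is.numeric(K)) {
    stop("`x` and `K` must be numeric", call. = FALSE)
  }
  if (any(K <= 0)) stop("half-saturation constant `K` must be > 0", call. = FALSE)
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  x3 <- x^3
  x3 / (K^3 + x3)
}

#' Capped sum of weighted drive terms
#'
#' Sums non-negative drive contributions (typically weighted Hill terms) and
#' caps the total at 1, so that a per-capita rate multiplied by the result
#' never exceeds its maximal value.  The cap is applied once to the summed
#' drive, not term by term.
#'
#' @param terms Numeric vector of non-negative contributions; may be empty,
#'   in which case the drive is 0.
#' @return `min(sum(terms), 1)`.
#' @examples
#' saturating_sum(c(0.3, 0.2))  # 0.5
#' saturating_sum(c(0.8, 0.8))  # 1
#' @export
saturating_sum <- function(terms) {
  if (length(terms) == 0) return(0)
  if (!is.numeric(terms)) stop("`terms` must be numeric", call. = FALSE)
  if (any(terms < 0)) stop("drive terms must be non-negative", call. = FALSE)
  min(sum(terms), 1)
}
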