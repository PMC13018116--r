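#' Erlang delay chain (linear chain trick)
#'
#' Represents a delayed input process as a cascade of `shape` first-order
#' reactions with common rate `rate`:
#' \deqn{dy_1/dt = k (u - y_1), \quad dy_i/dt = k (y_{i-1} - y_i),}
#' with the chain output `y_n`.  The impulse response of the cascade is the
#' Erlang density with rate `k` and shape `n`, so a unit of input reaches the
#' output after a random delay with mean `n / k` and standard deviation
#' `sqrt(n) / k`.  For `shape = 1` the chain reduces to a first-order lag.
#'
#' @param rate Chain rate constant `k` (per day), `> 0`.
#' @param shape Integer number of sequential steps `n >= 1`.
#' @return Object of class `delay_chain` with elements `rate`, `shape`.
#' @seealso [chain_rhs()], [delay_mean()], [delay_sd()]
#' @export
delay_chain <- function(rate, shape = 1L) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (is.na(shape) || shape < 1L) {
    stop("`shape` must be a positive integer", call. = FALSE)
  }
  structure(list(rate = rate, shape = shape), class = "delay_chain")
}

#' @export
print.delay_chain <- function(x, ...) {
  cat(sprintf("Erlang delay chain R[k = %g, n = %d]: mean %.3g d, sd %.3g d\n",
              x$rate, x$shape, delay_mean(x), delay_sd(x)))
  invisible(x)
}

#' Mean delay of a chain, `n / k` (days)
#' @param chain A [delay_chain()] object.
#' @export
delay_mean <- function(chain) chain$shape / chain$rate

#' Standard deviation of the chain delay, `sqrt(n) / k` (days)
#'
#' This is the Erlang standard deviation; together with [delay_mean()] it
#' gives coefficient of variation `1 / sqrt(n)`, so the chain shape controls
#' how sharply timed the delayed process is.
#' @param chain A [delay_chain()] object.
#' @export
delay_sd <- function(chain) sqrt(chain$shape) / chain$rate

#' Time derivatives of the chain state
#'
#' @param chain A [delay_chain()] object.
#' @param state Numeric vector of current chain intermediates `y_1..y_n`.
#' @param input Non-negative driving level `u(t)`.
#' @return Vector of derivatives of the same length as `state`.
#' @export
chain_rhs <- function(chain, state, input) {
  stopifnot(inherits(chain, "delay_chain"))
  n <- chain$shape
  if (length(state) != n) {
    stop(sprintf("chain state has length %d, expected %d", length(state), n),
         call. = FALSE)
  }
  if (input < 0) stop("chain input must be non-negative", call. = FALSE)
  k <- chain$rate
  dy <- k * (c(input, state[-n]) - state)
  dy
}

#' Chain output (the last intermediate)
#' @param chain A [delay_chain()] object.
#' @param state Chain state vector.
#' @export
chain_output <- function(chain, state) state[[chain$shape]]

#' Impulse response of a delay chain
#'
#' Integrates the chain from a unit impulse (all input delivered at `t = 0`
#' into `y_1`) and returns the output `y_n(t)` scaled as a density in time,
#' which equals the Erlang density `dgamma(t, shape = n, rate = k)`.  Mainly
#' used to verify chain normalisation and moments.
#'
#' @param chain A [delay_chain()] object.
#' @param times Non-negative times (days) at which to evaluate.
#' @return Data frame with columns `time` and `response`.
#' @export
chain_impulse_response <- function(chain, times) {
  stopifnot(inherits(chain, "delay_chain"))
  n <- chain$shape
  # a unit impulse of input makes y_1 jump to k; thereafter y_n(t) equals the
  # Erlang(n, k) density of arrival times at the chain output
  y0 <- c(chain$rate, rep(0, n - 1L))
  deriv <- function(t, y, parms) list(chain_rhs(chain, y, input = 0))
  out <- deSolve::lsoda(y0, times, deriv, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  data.frame(time = out[, 1L], response = out[, n + 1L])
}
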