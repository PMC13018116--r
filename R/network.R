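#' Weighted Hill drive term
#'
#' One contribution `weight * h(level, K)` to a gated rate, where `level` is
#' the current abundance of the named species (cell or cytokine).
#'
#' @param species Name of the driving species.
#' @param K Half-saturation constant for the cubic Hill gate.
#' @param weight Non-negative weight, default 1.
#' @export
drive_term <- function(species, K, weight = 1) {
  stopifnot(is.character(species), length(species) == 1L)
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (weight < 0) stop("`weight` must be >= 0", call. = FALSE)
  structure(list(species = species, K = K, weight = weight),
            class = "drive_term")
}

#' Cell species of a generic interaction network
#'
#' @param name Species name.
#' @param infiltration `NULL`, or `list(rate =, drive =, delay =)`:
#'   infiltration at `rate` gated by the capped sum of `drive` terms
#'   (a list of [drive_term()]; `NULL` means ungated), optionally routed
#'   through a [delay_chain()] given as `delay`.
#' @param activation `NULL`, or list of `list(from =, rate =, drive =)` terms
#'   of the form `rate * gate * (x_from - x_self)`.
#' @param proliferation `NULL`, or `list(rate =, drive =)` logistic growth
#'   `rate * gate * (1 - x / capacity) * x`.
#' @param capacity Carrying capacity `omega`; `Inf` disables the bound.
#' @param death Per-capita removal rate `delta`.
#' @export
cell_species <- function(name, infiltration = NULL, activation = NULL,
                         proliferation = NULL, capacity = Inf, death = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (death < 0 || capacity <= 0) {
    stop("`death` must be >= 0 and `capacity` > 0", call. = FALSE)
  }
  structure(list(name = name, infiltration = infiltration,
                 activation = activation, proliferation = proliferation,
                 capacity = capacity, death = death),
            class = "cell_species")
}

#' Cytokine species of a generic interaction network
#'
#' Dynamics `dc/dt = sum(q_n x_n) - sum(lambda_n h(c, K) x_n) - eta c`:
#' secretion by producing cells, Hill-gated endocytosis by consuming cells,
#' and first-order degradation.
#'
#' @param name Species name.
#' @param secretion Named numeric vector of secretion rates `q` by cell.
#' @param endocytosis Named numeric vector of maximal uptake rates `lambda`
#'   by consuming cell.
#' @param K Half-saturation constant of the uptake gate.
#' @param degradation First-order degradation rate `eta`.
#' @export
cytokine_species <- function(name, secretion = numeric(), endocytosis = numeric(),
                             K = 1, degradation = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  if (degradation < 0 || any(secretion < 0) || any(endocytosis < 0)) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(list(name = name, secretion = secretion,
                 endocytosis = endocytosis, K = K, degradation = degradation),
            class = "cytokine_species")
}

#' Declarative specification of a cell-cytokine interaction network
#'
#' Bundles cell and cytokine species into a validated network from which
#' [assemble_rhs()] builds the coupled ODE right-hand side
#' \deqn{dx_i/dt = R[\beta_i(\cdot), n_i] + \sum_n \alpha_{in}(\cdot)(x_n - x_i)
#'   + [\gamma_i(\cdot)(1 - x_i/\omega_i) - \delta_i] x_i,}
#' \deqn{dc_j/dt = \sum_n q_{nj} x_n - \lambda_{nj} h[c_j, K_j] x_n - \eta_j c_j.}
#'
#' @param cells List of [cell_species()].
#' @param cytokines List of [cytokine_species()].
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(cells, cytokines = list()) {
  spec <- structure(list(cells = cells, cytokines = cytokines),
                    class = "network_spec")
  validate_network_spec(spec)
  spec
}

#' Validate a network specification
#'
#' Checks that every referenced species exists, that rates are non-negative,
#' and that every cytokine is either consumed by at least one cell or
#' degraded.  Called by [network_spec()]; exported so deserialised specs can
#' be re-checked.
#'
#' @param spec A `network_spec`.
#' @return `spec`, invisibly, or an error describing every violation found.
#' @export
validate_network_spec <- function(spec) {
  stopifnot(inherits(spec, "network_spec"))
  cn <- vapply(spec$cells, `[[`, "", "name")
  kn <- vapply(spec$cytokines, `[[`, "", "name")
  all_names <- c(cn, kn)
  bad <- character()
  if (anyDuplicated(all_names)) {
    bad <- c(bad, sprintf("duplicated species names: %s",
                          paste(unique(all_names[duplicated(all_names)]), collapse = ", ")))
  }
  chk_drive <- function(drive, where) {
    for (d in drive) {
      if (!inherits(d, "drive_term")) {
        bad <<- c(bad, sprintf("%s: drive entries must be drive_term objects", where))
      } else if (!d$species %in% all_names) {
        bad <<- c(bad, sprintf("%s: unknown species '%s'", where, d$species))
      }
    }
  }
  for (cl in spec$cells) {
    if (!is.null(cl$infiltration)) {
      if (cl$infiltration$rate < 0) bad <- c(bad, sprintf("%s: negative infiltration rate", cl$name))
      chk_drive(cl$infiltration$drive, sprintf("%s infiltration", cl$name))
      if (!is.null(cl$infiltration$delay) && !inherits(cl$infiltration$delay, "delay_chain")) {
        bad <- c(bad, sprintf("%s: `delay` must be a delay_chain", cl$name))
      }
    }
    for (a in cl$activation) {
      if (!a$from %in% cn) bad <- c(bad, sprintf("%s activation: unknown cell '%s'", cl$name, a$from))
      if (a$rate < 0) bad <- c(bad, sprintf("%s: negative activation rate", cl$name))
      chk_drive(a$drive, sprintf("%s activation", cl$name))
    }
    if (!is.null(cl$proliferation)) {
      if (cl$proliferation$rate < 0) bad <- c(bad, sprintf("%s: negative proliferation rate", cl$name))
      chk_drive(cl$proliferation$drive, sprintf("%s proliferation", cl$name))
    }
  }
  for (cy in spec$cytokines) {
    for (src in names(cy$secretion)) {
      if (!src %in% cn) bad <- c(bad, sprintf("%s secretion: unknown cell '%s'", cy$name, src))
    }
    for (src in names(cy$endocytosis)) {
      if (!src %in% cn) bad <- c(bad, sprintf("%s endocytosis: unknown cell '%s'", cy$name, src))
    }
    if (length(cy$endocytosis) == 0 && cy$degradation <= 0) {
      bad <- c(bad, sprintf("cytokine %s is neither consumed nor degraded", cy$name))
    }
  }
  if (length(bad)) {
    stop("invalid network_spec:\n  ", paste(bad, collapse = "\n  "), call. = FALSE)
  }
  invisible(spec)
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec: %d cell species (%s), %d cytokines (%s)\n",
              length(x$cells), paste(vapply(x$cells, `[[`, "", "name"), collapse = ", "),
              length(x$cytokines),
              paste(vapply(x$cytokines, `[[`, "", "name"), collapse = ", ")))
  invisible(x)
}

#' Names of the full state vector of a network
#'
#' Named species come first (cells, then cytokines); the delay-chain
#' intermediates of each infiltrating cell follow, contiguously, in cell
#' order, named `<cell>.y<i>`.  This ordering is part of the public contract.
#'
#' @param spec A `network_spec`.
#' @export
network_state_names <- function(spec) {
  cn <- vapply(spec$cells, `[[`, "", "name")
  kn <- vapply(spec$cytokines, `[[`, "", "name")
  chains <- character()
  for (cl in spec$cells) {
    dl <- cl$infiltration$delay
    if (!is.null(dl)) {
      chains <- c(chains, paste0(cl$name, ".y", seq_len(dl$shape)))
    }
  }
  c(cn, kn, chains)
}

#' Build the ODE right-hand side of a network
#'
#' @param spec A validated `network_spec`.
#' @return A function `f(t, state, parms = NULL)` returning `list(dstate)`,
#'   directly usable with the \pkg{deSolve} integrators.  The state layout is
#'   given by [network_state_names()].
#' @export
assemble_rhs <- function(spec) {
  validate_network_spec(spec)
  nm <- network_state_names(spec)
  cn <- vapply(spec$cells, `[[`, "", "name")
  kn <- vapply(spec$cytokines, `[[`, "", "name")
  n_named <- length(cn) + length(kn)

  gate <- function(drive, lv) {
    if (is.null(drive) || length(drive) == 0) return(1)
    saturating_sum(vapply(drive, function(d) d$weight * hill(lv[[d$species]], d$K),
                          numeric(1)))
  }

  function(t, state, parms = NULL) {
    if (length(state) != length(nm)) {
      stop(sprintf("state has length %d, expected %d", length(state), length(nm)),
           call. = FALSE)
    }
    lv <- as.list(stats::setNames(state[seq_len(n_named)], c(cn, kn)))
    d <- numeric(length(state))
    names(d) <- nm
    ci <- n_named  # cursor past named species into chain block
    for (cl in spec$cells) {
      xi <- lv[[cl$name]]
      dx <- -cl$death * xi
      if (!is.null(cl$proliferation)) {
        g <- gate(cl$proliferation$drive, lv)
        dx <- dx + cl$proliferation$rate * g * (1 - xi / cl$capacity) * xi
      }
      for (a in cl$activation) {
        g <- gate(a$drive, lv)
        dx <- dx + a$rate * g * (lv[[a$from]] - xi)
      }
      inf <- cl$infiltration
      if (!is.null(inf)) {
        u <- inf$rate * gate(inf$drive, lv)
        if (is.null(inf$delay)) {
          dx <- dx + u
        } else {
          nch <- inf$delay$shape
          ys <- state[ci + seq_len(nch)]
          d[ci + seq_len(nch)] <- chain_rhs(inf$delay, ys, u)
          dx <- dx + chain_output(inf$delay, ys)
          ci <- ci + nch
        }
      }
      d[cl$name] <- dx
    }
    for (cy in spec$cytokines) {
      cj <- lv[[cy$name]]
      dc <- -cy$degradation * cj
      for (src in names(cy$secretion)) dc <- dc + cy$secretion[[src]] * lv[[src]]
      h <- hill(cj, cy$K)
      for (src in names(cy$endocytosis)) dc <- dc - cy$endocytosis[[src]] * h * lv[[src]]
      d[cy$name] <- dc
    }
    list(d)
  }
}

#' Integrate a generic network
#'
#' Thin wrapper around [deSolve::lsoda()] using [assemble_rhs()].
#'
#' @param spec A `network_spec`.
#' @param state0 Initial values for the named species (missing entries and
#'   all chain intermediates start at 0).
#' @param times Output times (days).
#' @param rtol,atol Solver tolerances.
#' @return Data frame with column `time` and one column per state variable.
#' @export
simulate_network <- function(spec, state0, times, rtol = 1e-8, atol = 1e-10) {
  nm <- network_state_names(spec)
  y0 <- stats::setNames(numeric(length(nm)), nm)
  if (!all(names(state0) %in% nm)) {
    stop("unknown state names: ",
         paste(setdiff(names(state0), nm), collapse = ", "), call. = FALSE)
  }
  y0[names(state0)] <- state0
  out <- deSolve::lsoda(y0, times, assemble_rhs(spec), parms = NULL,
                        rtol = rtol, atol = atol)
  df <- as.data.frame(out)
  names(df)[1] <- "time"
  df
}
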