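# Scenario configuration files and run manifests.
#
# A scenario file is a YAML document with up to four top-level blocks:
#   genotype: NZBW | WT
#   parameters:  named overrides of lupus_parameters() (optional)
#   schedule:    polyic_window, depletion_targets, depletion_strength,
#                depletion_window, feedback_knockouts (optional)
#   telegraph:   tau_on, tau_off, cv_on, xi (optional; presence marks a
#                hybrid scenario)
# Unknown keys anywhere are rejected with the offending location.

#' Load a simulation scenario
#'
#' @param path YAML scenario file, or the name of a shipped preset (one of
#'   `lupusim_presets()`).
#' @return List with `params` ([lupus_parameters()]), `schedule`
#'   ([intervention_schedule()]) and `telegraph` (a [telegraph_config()] or
#'   `NULL`), plus `name`.
#' @examples
#' sc <- load_scenario("nzbw_polyic")
#' sc$schedule
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) {
    builtin <- system.file("scenarios", paste0(path, ".yaml"), package = "lupusim")
    if (nzchar(builtin)) path <- builtin
    else stop(sprintf("scenario file or preset '%s' not found", path), call. = FALSE)
  }
  obj <- yaml::read_yaml(path)
  chk_keys(obj, c("name", "genotype", "preset", "parameters", "schedule",
                  "telegraph"), path)
  genotype <- obj$genotype %||% "NZBW"
  sch <- obj$schedule %||% list()
  chk_keys(sch, c("polyic_window", "depletion_targets", "depletion_strength",
                  "depletion_window", "feedback_knockouts"),
           paste0(path, ": schedule"))
  # an explicit null polyic_window marks an untreated scenario; absence of
  # the key keeps the default window
  polyic <- if ("polyic_window" %in% names(sch)) sch$polyic_window else c(19, 23)
  schedule <- intervention_schedule(
    genotype = genotype,
    polyic_window = if (is.null(polyic)) NULL else as.numeric(polyic),
    depletion_targets = as.character(sch$depletion_targets %||% character()),
    depletion_strength = sch$depletion_strength %||% 0.8,
    depletion_window = as.numeric(sch$depletion_window %||% c(19, 25)),
    feedback_knockouts = as.character(sch$feedback_knockouts %||% character()))
  pars <- obj$parameters %||% list()
  unknown <- setdiff(names(pars), .param_names)
  if (length(unknown)) {
    stop(sprintf("%s: parameters: unknown keys: %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  params <- do.call(lupus_parameters,
                    c(list(genotype = genotype,
                           preset = obj$preset %||% "depletion_scaled"), pars))
  telegraph <- NULL
  if (!is.null(obj$telegraph)) {
    chk_keys(obj$telegraph, c("tau_on", "tau_off", "cv_on", "xi"),
             paste0(path, ": telegraph"))
    telegraph <- do.call(telegraph_config, obj$telegraph)
  }
  list(name = obj$name %||% sub("\\.ya?ml$", "", basename(path)),
       params = params, schedule = schedule, telegraph = telegraph)
}

#' Names of the shipped scenario presets
#' @export
lupusim_presets <- function() {
  sub("\\.yaml$", "", list.files(system.file("scenarios", package = "lupusim"),
                                 pattern = "\\.yaml$"))
}

#' Save a scenario to YAML
#'
#' Inverse of [load_scenario()]; `load_scenario(save_scenario(x, f))`
#' reproduces the same objects.
#'
#' @param scenario List as returned by [load_scenario()].
#' @param path Output file.
#' @export
save_scenario <- function(scenario, path) {
  sch <- scenario$schedule
  obj <- list(name = scenario$name,
              genotype = sch$genotype,
              preset = attr(scenario$params, "preset"),
              parameters = non_default_parameters(scenario$params),
              schedule = list(
                polyic_window = sch$polyic_window,
                depletion_targets = sch$depletion_targets,
                depletion_strength = sch$depletion_strength,
                depletion_window = sch$depletion_window,
                feedback_knockouts = sch$feedback_knockouts))
  if (!is.null(scenario$telegraph)) {
    tg <- scenario$telegraph
    obj$telegraph <- list(tau_on = tg$tau_on, tau_off = tg$tau_off,
                          cv_on = tg$cv_on, xi = tg$xi)
  }
  yaml::write_yaml(obj, path)
  invisible(path)
}

non_default_parameters <- function(params) {
  base <- lupus_parameters(genotype = attr(params, "genotype"),
                           preset = attr(params, "preset"))
  out <- list()
  for (nm in .param_names) {
    if (!identical(params[[nm]], base[[nm]])) out[[nm]] <- params[[nm]]
  }
  out
}

#' Run manifest
#'
#' Provenance record sufficient to re-run a command bit-compatibly: the
#' scenario, parameter values and their hash, seeds, solver settings and
#' package version.
#'
#' @param scenario Scenario list (see [load_scenario()]).
#' @param seed Integer seed used (or `NULL` for deterministic commands).
#' @param command Name of the command that produced the outputs.
#' @param extra Named list of additional settings to record.
#' @return List of class `run_manifest`.
#' @export
run_manifest <- function(scenario, seed = NULL, command = "simulate",
                         extra = list()) {
  pv <- unlist(scenario$params[.param_names])
  manifest <- list(
    command = command,
    scenario = scenario$name,
    genotype = scenario$schedule$genotype,
    preset = attr(scenario$params, "preset"),
    parameters = as.list(pv),
    parameter_hash = param_hash(scenario$params),
    schedule = scenario$schedule[c("polyic_window", "depletion_targets",
                                   "depletion_strength", "depletion_window",
                                   "feedback_knockouts")],
    telegraph = if (!is.null(scenario$telegraph)) {
      scenario$telegraph[c("tau_on", "tau_off", "cv_on", "n_on", "xi")]
    },
    seed = seed,
    tool = "lupusim",
    version = as.character(utils::packageVersion("lupusim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  class(manifest) <- "run_manifest"
  manifest
}

# Order-stable numeric hash of the parameter record (no external digest
# dependency): polynomial rolling hash over the full-precision formatted
# values, in exact double arithmetic (all intermediates < 2^53).
param_hash <- function(params) {
  s <- paste(sprintf("%s=%.17g", .param_names, unlist(params[.param_names])),
             collapse = ";")
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 257 + b) %% m
  sprintf("%08x", h)
}

#' Write a manifest (JSON)
#' @param manifest A [run_manifest()].
#' @param path Output file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}
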