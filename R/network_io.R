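# YAML serialisation of network specifications.  The on-disk format mirrors
# the constructor arguments; unknown keys are rejected on read so that typos
# in hand-written files fail loudly.

drive_to_list <- function(d) list(species = d$species, K = d$K, weight = d$weight)
drive_from_list <- function(l, where) {
  chk_keys(l, c("species", "K", "weight"), where)
  drive_term(l$species, l$K, l$weight %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

chk_keys <- function(l, allowed, where) {
  extra <- setdiff(names(l), allowed)
  if (length(extra)) {
    stop(sprintf("%s: unknown keys: %s", where, paste(extra, collapse = ", ")),
         call. = FALSE)
  }
}

#' Write a network specification to a YAML file
#' @param spec A `network_spec`.
#' @param path Output file path.
#' @export
write_network_spec <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  enc_cell <- function(cl) {
    out <- list(name = cl$name, capacity = cl$capacity, death = cl$death)
    if (!is.null(cl$infiltration)) {
      inf <- list(rate = cl$infiltration$rate)
      if (!is.null(cl$infiltration$drive)) {
        inf$drive <- lapply(cl$infiltration$drive, drive_to_list)
      }
      if (!is.null(cl$infiltration$delay)) {
        inf$delay <- list(rate = cl$infiltration$delay$rate,
                          shape = cl$infiltration$delay$shape)
      }
      out$infiltration <- inf
    }
    if (length(cl$activation)) {
      out$activation <- lapply(cl$activation, function(a) {
        al <- list(from = a$from, rate = a$rate)
        if (!is.null(a$drive)) al$drive <- lapply(a$drive, drive_to_list)
        al
      })
    }
    if (!is.null(cl$proliferation)) {
      pr <- list(rate = cl$proliferation$rate)
      if (!is.null(cl$proliferation$drive)) {
        pr$drive <- lapply(cl$proliferation$drive, drive_to_list)
      }
      out$proliferation <- pr
    }
    out
  }
  enc_cyt <- function(cy) {
    list(name = cy$name, K = cy$K, degradation = cy$degradation,
         secretion = as.list(cy$secretion), endocytosis = as.list(cy$endocytosis))
  }
  obj <- list(cells = lapply(spec$cells, enc_cell),
              cytokines = lapply(spec$cytokines, enc_cyt))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a network specification from a YAML file
#' @param path File written by [write_network_spec()] (or hand-authored in
#'   the same format).
#' @return A validated `network_spec`.
#' @export
read_network_spec <- function(path) {
  obj <- yaml::read_yaml(path)
  chk_keys(obj, c("cells", "cytokines"), path)
  dec_cell <- function(l) {
    chk_keys(l, c("name", "capacity", "death", "infiltration", "activation",
                  "proliferation"), paste0("cell ", l$name %||% "?"))
    inf <- NULL
    if (!is.null(l$infiltration)) {
      chk_keys(l$infiltration, c("rate", "drive", "delay"),
               paste0(l$name, " infiltration"))
      inf <- list(rate = l$infiltration$rate,
                  drive = if (!is.null(l$infiltration$drive)) {
                    lapply(l$infiltration$drive, drive_from_list,
                           where = paste0(l$name, " infiltration drive"))
                  },
                  delay = if (!is.null(l$infiltration$delay)) {
                    delay_chain(l$infiltration$delay$rate, l$infiltration$delay$shape)
                  })
    }
    act <- NULL
    if (!is.null(l$activation)) {
      act <- lapply(l$activation, function(a) {
        chk_keys(a, c("from", "rate", "drive"), paste0(l$name, " activation"))
        list(from = a$from, rate = a$rate,
             drive = if (!is.null(a$drive)) {
               lapply(a$drive, drive_from_list,
                      where = paste0(l$name, " activation drive"))
             })
      })
    }
    pr <- NULL
    if (!is.null(l$proliferation)) {
      chk_keys(l$proliferation, c("rate", "drive"), paste0(l$name, " proliferation"))
      pr <- list(rate = l$proliferation$rate,
                 drive = if (!is.null(l$proliferation$drive)) {
                   lapply(l$proliferation$drive, drive_from_list,
                          where = paste0(l$name, " proliferation drive"))
                 })
    }
    cell_species(l$name, infiltration = inf, activation = act,
                 proliferation = pr,
                 capacity = l$capacity %||% Inf, death = l$death %||% 0)
  }
  dec_cyt <- function(l) {
    chk_keys(l, c("name", "K", "degradation", "secretion", "endocytosis"),
             paste0("cytokine ", l$name %||% "?"))
    cytokine_species(l$name,
                     secretion = unlist(l$secretion) %||% numeric(),
                     endocytosis = unlist(l$endocytosis) %||% numeric(),
                     K = l$K %||% 1, degradation = l$degradation %||% 0)
  }
  network_spec(lapply(obj$cells, dec_cell),
               lapply(obj$cytokines %||% list(), dec_cyt))
}
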