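#' Kinetic schemes for receptors and transporters
#'
#' A kinetic scheme is a labelled continuous-time Markov model: a set of
#' molecular states, one initial state, one designated conducting (open)
#' state for receptors, and a list of transitions. Each transition carries a
#' rate constant and a ligand order: order 0 transitions are unimolecular
#' (rate in 1/s), order 1 transitions are glutamate-dependent (rate in
#' 1/(M s), multiplied by the local free glutamate concentration at run
#' time). Each state records how many glutamate molecules it holds bound, so
#' the engine can conserve ligand exactly: a transition that raises the
#' bound count consumes free glutamate, one that lowers it either releases
#' glutamate back to the compartment or, if flagged `consumes`, removes it
#' permanently (transporter uptake).
#'
#' Scheme files are plain text, one directive per line:
#' \preformatted{
#' name    <label>
#' state   <label> <bound_glu> [open]
#' initial <label>
#' transition <from> <to> <rate> <ligand_order> [consumes]
#' }
#'
#' @param states character vector of state labels.
#' @param bound_glu integer vector, glutamate molecules bound in each state.
#' @param initial label of the initial state.
#' @param open label of the open state, or `NA` for transporter schemes.
#' @param transitions data.frame with columns `from`, `to`, `rate`,
#'   `ligand_order`, `consumes`.
#' @param name scheme label.
#' @return Object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(states, bound_glu, initial, open, transitions,
                           name = "scheme") {
  sch <- structure(list(
    name = name,
    states = as.character(states),
    bound_glu = as.integer(bound_glu),
    initial = initial,
    open = open,
    transitions = transitions
  ), class = "kinetic_scheme")
  validate_scheme(sch)
  sch
}

validate_scheme <- function(sch) {
  st <- sch$states
  if (anyDuplicated(st)) stop("duplicate state labels in scheme", call. = FALSE)
  if (length(sch$bound_glu) != length(st))
    stop("bound_glu must have one entry per state", call. = FALSE)
  if (!(sch$initial %in% st))
    stop(sprintf("initial state '%s' not among states", sch$initial),
         call. = FALSE)
  if (!is.na(sch$open) && !(sch$open %in% st))
    stop(sprintf("open state '%s' not among states", sch$open), call. = FALSE)
  tr <- sch$transitions
  need <- c("from", "to", "rate", "ligand_order", "consumes")
  if (!all(need %in% names(tr)))
    stop("transitions must have columns from, to, rate, ligand_order, consumes",
         call. = FALSE)
  bad <- setdiff(unique(c(tr$from, tr$to)), st)
  if (length(bad))
    stop("transition references unknown state(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(!is.finite(tr$rate) | tr$rate < 0))
    stop("all rate constants must be finite and >= 0", call. = FALSE)
  if (!all(tr$ligand_order %in% c(0, 1)))
    stop("ligand_order must be 0 or 1", call. = FALSE)
  # bound-glutamate bookkeeping must be consistent with ligand orders
  dglu <- sch$bound_glu[match(tr$to, st)] - sch$bound_glu[match(tr$from, st)]
  if (any(dglu > 0 & tr$ligand_order != 1))
    stop("transition increasing bound glutamate must have ligand_order 1",
         call. = FALSE)
  if (any(tr$consumes & dglu >= 0))
    stop("a 'consumes' transition must lower the bound glutamate count",
         call. = FALSE)
  # every state reachable from the initial state
  reach <- sch$initial
  repeat {
    nxt <- unique(c(reach, tr$to[tr$from %in% reach & tr$rate > 0]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  unreachable <- setdiff(st, reach)
  if (length(unreachable))
    stop("state(s) unreachable from initial state: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  invisible(sch)
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf("<kinetic_scheme '%s'>: %d states (initial %s%s), %d transitions\n",
              x$name, length(x$states), x$initial,
              if (!is.na(x$open)) paste0(", open ", x$open) else "",
              nrow(x$transitions)))
  invisible(x)
}

#' Read a kinetic scheme file
#'
#' @param path path to a scheme file (see [kinetic_scheme()] for the format).
#' @return validated `kinetic_scheme`.
#' @export
read_kinetic_scheme <- function(path) {
  if (!file.exists(path)) stop("scheme file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  states <- character()
  bound <- integer()
  open <- NA_character_
  initial <- NA_character_
  name <- "scheme"
  tr <- list()
  for (ln in lines) {
    tok <- strsplit(ln, "\\s+")[[1]]
    switch(tok[1],
      name = { name <- tok[2] },
      state = {
        states <- c(states, tok[2])
        bound <- c(bound, as.integer(tok[3]))
        if (length(tok) >= 4 && tok[4] == "open") {
          if (!is.na(open)) stop("more than one open state declared", call. = FALSE)
          open <- tok[2]
        }
      },
      initial = { initial <- tok[2] },
      transition = {
        tr[[length(tr) + 1L]] <- data.frame(
          from = tok[2], to = tok[3], rate = as.numeric(tok[4]),
          ligand_order = as.integer(tok[5]),
          consumes = length(tok) >= 6 && tok[6] == "consumes")
      },
      stop("unknown scheme directive: ", tok[1], call. = FALSE)
    )
  }
  if (is.na(initial)) stop("scheme file declares no initial state", call. = FALSE)
  kinetic_scheme(states, bound, initial, open, do.call(rbind, tr), name)
}

#' Write a kinetic scheme file
#'
#' Round-trips with [read_kinetic_scheme()]: writing then reading reproduces
#' an identical transition set.
#'
#' @param scheme a `kinetic_scheme`.
#' @param path output path.
#' @export
write_kinetic_scheme <- function(scheme, path) {
  out <- c(paste("name", scheme$name))
  for (i in seq_along(scheme$states)) {
    s <- paste("state", scheme$states[i], scheme$bound_glu[i])
    if (!is.na(scheme$open) && scheme$states[i] == scheme$open)
      s <- paste(s, "open")
    out <- c(out, s)
  }
  out <- c(out, paste("initial", scheme$initial))
  tr <- scheme$transitions
  for (i in seq_len(nrow(tr))) {
    s <- paste("transition", tr$from[i], tr$to[i],
               format(tr$rate[i], digits = 15), tr$ligand_order[i])
    if (tr$consumes[i]) s <- paste(s, "consumes")
    out <- c(out, s)
  }
  writeLines(out, path)
  invisible(path)
}

#' Bundled default schemes
#'
#' `default_ampa_scheme()` returns the 7-state AMPA receptor scheme (closed
#' states C0--C5 and the conducting state O) with the rate constants of
#' Jonas, Major & Sakmann (1993) as widely reproduced in synaptic modeling
#' studies. `default_transporter_scheme()` returns a simplified three-state
#' glutamate transporter cycle (free, bound, translocating) with rates in
#' the range reported for glial transporters (cf. Franks, Bartol &
#' Sejnowski, 2002); the translocation step removes glutamate from the
#' extracellular space.
#'
#' @return a `kinetic_scheme`.
#' @export
default_ampa_scheme <- function() {
  read_kinetic_scheme(system.file("extdata", "ampa_jonas1993.scheme",
                                  package = "synsurr", mustWork = TRUE))
}

#' @rdname default_ampa_scheme
#' @export
default_transporter_scheme <- function() {
  read_kinetic_scheme(system.file("extdata", "glt_3state.scheme",
                                  package = "synsurr", mustWork = TRUE))
}
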