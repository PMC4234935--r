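# Ordered state lists and the successor/predecessor operators.
#
# The order of a state list is exactly its declaration order; succ/pred
# follow that order, undefined at the boundary unless the list is
# circular (the last element then connects back to the first).

#' Resolve a site definition to its concrete state list
#'
#' Integer ranges are inclusive on both ends (`{0:10}` has 11 states);
#' symbolic bounds are statically evaluated over fixed global
#' quantities, flooring non-integer values. Enumerated lists are kept in
#' declaration order, verbatim.
#'
#' @param site a site definition (from [parse_species()] or a model
#'   species), or a character vector of labels for convenience.
#' @param globals fixed global quantities (model, list, or named numeric
#'   vector).
#' @param circular circular flag when `site` is given as a plain label
#'   vector.
#' @return an object of class `msl_statelist`: list with `labels`
#'   (character, declaration order), `numeric` (are all labels
#'   integers?), `values` (numeric labels or NA) and `circular`.
#'   A reversed range (`lo > hi`) yields an empty list with attribute
#'   `"empty_range"` set, which callers surface as a warning.
#' @examples
#' resolve_state_list(parse_species("Cdh1(p{0:10})")$sites[[1]])$labels
#' state_succ(resolve_state_list(c("2", "4", "6", "8", "0")), "2")
#' @export
resolve_state_list <- function(site, globals = list(), circular = FALSE) {
  if (is.character(site)) {
    return(new_statelist(site, circular))
  }
  switch(site$kind,
    empty = new_statelist(character(), isTRUE(site$circular)),
    enumset = new_statelist(site$labels, isTRUE(site$circular)),
    range = {
      lo <- evaluate_static(site$lo, globals)
      hi <- evaluate_static(site$hi, globals)
      if (lo > hi) {
        sl <- new_statelist(character(), isTRUE(site$circular))
        attr(sl, "empty_range") <- sprintf("range {%s:%s} is empty (lo > hi)",
                                           format_num(lo), format_num(hi))
        sl
      } else {
        new_statelist(as.character(seq.int(lo, hi)), isTRUE(site$circular))
      }
    },
    stop("unknown site kind: ", site$kind))
}

new_statelist <- function(labels, circular = FALSE) {
  values <- suppressWarnings(as.numeric(labels))
  numeric <- length(labels) > 0 && !anyNA(values) &&
    all(values == round(values))
  structure(list(labels = labels, numeric = numeric,
                 values = if (numeric) values else rep(NA_real_, length(labels)),
                 circular = circular),
            class = "msl_statelist")
}

#' Successor and predecessor of a state
#'
#' `state_succ` maps a state to the next label in declaration order, and
#' `state_pred` to the previous one. On a circular list the last element
#' connects back to the first. Applying `succ` to the last state (or
#' `pred` to the first) of a non-circular list is an error: that
#' successor is not defined.
#'
#' @param states an `msl_statelist` from [resolve_state_list()].
#' @param s a state label (character or number).
#' @return the resulting state label (character).
#' @examples
#' sl <- resolve_state_list(c("2", "4", "6", "8", "0"))
#' state_succ(sl, 2)  # "4"
#' @export
state_succ <- function(states, s) {
  state_step(states, s, +1L, "successor")
}

#' @rdname state_succ
#' @export
state_pred <- function(states, s) {
  state_step(states, s, -1L, "predecessor")
}

state_step <- function(states, s, dir, what) {
  s <- as.character(s)
  i <- match(s, states$labels)
  if (is.na(i)) {
    stop(sprintf("state '%s' is not in the state list {%s}", s,
                 paste(states$labels, collapse = ",")), call. = FALSE)
  }
  j <- i + dir
  n <- length(states$labels)
  if (j < 1L || j > n) {
    if (states$circular) {
      j <- ((j - 1L) %% n) + 1L
    } else {
      stop(sprintf("the %s of state %s is not defined", what, s),
           call. = FALSE)
    }
  }
  states$labels[[j]]
}

apply_state_op <- function(states, s, op) {
  if (is.null(op)) as.character(s)
  else if (op == "succ") state_succ(states, s)
  else state_pred(states, s)
}

# Labels of `states` admitted by a reference pattern. Integer-range
# patterns select the labels whose numeric value falls inside [lo, hi]
# (set intersection with the state list); order follows the state list.
# Throws msl_static_error / stop() on structural problems -- validate()
# catches and grades them, the expander runs only on validated models.
pattern_admitted <- function(pat, states, globals) {
  if (is.null(pat) || identical(pat$kind, "any")) return(states$labels)
  switch(pat$kind,
    fixed = {
      if (!pat$label %in% states$labels) {
        stop(sprintf("state '%s' is not in the state list {%s}", pat$label,
                     paste(states$labels, collapse = ",")), call. = FALSE)
      }
      pat$label
    },
    enumset = {
      bad <- setdiff(pat$labels, states$labels)
      if (length(bad)) {
        stop(sprintf("state '%s' is not in the state list {%s}", bad[[1]],
                     paste(states$labels, collapse = ",")), call. = FALSE)
      }
      states$labels[states$labels %in% pat$labels]
    },
    range = {
      if (!states$numeric) {
        stop("a numeric range pattern cannot select from a non-numeric state list",
             call. = FALSE)
      }
      lo <- evaluate_static(pat$lo, globals)
      hi <- evaluate_static(pat$hi, globals)
      states$labels[states$values >= lo & states$values <= hi]
    },
    stop(sprintf("pattern of kind '%s' does not select reactant states", pat$kind),
         call. = FALSE))
}

#' @export
print.msl_statelist <- function(x, ...) {
  cat(sprintf("<state list> {%s}%s\n", paste(x$labels, collapse = ","),
              if (x$circular) " circular" else ""))
  invisible(x)
}
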