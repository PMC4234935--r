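# Flat CSV tables (species / reactions / parameters) and model size
# statistics. Comma-separated, quoted where needed, UTF-8, header row,
# deterministic column order.

#' Tabulate a flat model
#'
#' @param flat an `msl_flat_model`.
#' @return `flat_species_table`: data.frame with columns name, base,
#'   states, initial, assignment; `flat_reaction_table`: name, reaction
#'   (the flat reaction string), kinetic_law; `flat_parameter_table`:
#'   name, role, value, expression.
#' @export
flat_species_table <- function(flat) {
  rule_expr <- stats::setNames(
    vapply(flat$rules, `[[`, "", "expr_text"),
    vapply(flat$rules, `[[`, "", "variable"))
  n <- length(flat$species)
  data.frame(
    name = vapply(flat$species, `[[`, "", "name"),
    base = vapply(flat$species, `[[`, "", "base"),
    states = vapply(flat$species, function(s) state_key(names(s$states), s$states), ""),
    initial = vapply(flat$species, function(s) s$initial %||% NA_real_, 1),
    assignment = vapply(flat$species, function(s) {
      e <- unname(rule_expr[s$name])
      if (is.na(e)) "" else e
    }, ""),
    stringsAsFactors = FALSE)[seq_len(n), , drop = FALSE]
}

#' @rdname flat_species_table
#' @export
flat_reaction_table <- function(flat) {
  data.frame(
    name = vapply(flat$reactions, `[[`, "", "name"),
    reaction = vapply(flat$reactions, flat_reaction_string, ""),
    kinetic_law = vapply(flat$reactions, `[[`, "", "kinetic_text"),
    stringsAsFactors = FALSE)
}

flat_reaction_string <- function(r) {
  txt <- paste0(paste(r$reactants, collapse = " + "), " -> ",
                paste(r$products, collapse = " + "))
  if (length(r$modifiers)) txt <- paste0(txt, "; ", paste(r$modifiers, collapse = " + "))
  txt
}

#' @rdname flat_species_table
#' @export
flat_parameter_table <- function(flat) {
  species_names <- vapply(flat$species, `[[`, "", "name")
  assigned <- Filter(function(r) !r$variable %in% species_names, flat$rules)
  data.frame(
    name = c(vapply(flat$parameters, `[[`, "", "name"),
             vapply(assigned, `[[`, "", "variable")),
    role = c(rep("fixed", length(flat$parameters)),
             rep("assigned", length(assigned))),
    value = c(vapply(flat$parameters, `[[`, 1, "value"),
              rep(NA_real_, length(assigned))),
    expression = c(rep("", length(flat$parameters)),
                   vapply(assigned, `[[`, "", "expr_text")),
    stringsAsFactors = FALSE)
}

#' Write a flat model as CSV tables
#'
#' Writes `species.csv`, `reactions.csv` and `parameters.csv` into a
#' directory.
#'
#' @param flat an `msl_flat_model`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tables <- function(flat, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(flat_species_table(flat), file.path(dir, "species.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(flat_reaction_table(flat), file.path(dir, "reactions.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(flat_parameter_table(flat), file.path(dir, "parameters.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}

#' Read flat CSV tables back
#'
#' @param dir directory written by [write_tables()].
#' @return list of the three data.frames (`species`, `reactions`,
#'   `parameters`).
#' @export
read_tables <- function(dir) {
  list(
    species = utils::read.csv(file.path(dir, "species.csv"),
                              stringsAsFactors = FALSE,
                              colClasses = c(states = "character",
                                             assignment = "character")),
    reactions = utils::read.csv(file.path(dir, "reactions.csv"),
                                stringsAsFactors = FALSE),
    parameters = utils::read.csv(file.path(dir, "parameters.csv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = c(expression = "character")))
}

#' Size statistics of a compact/flat model pair
#'
#' The reduction fraction `1 - compact/flat` per category quantifies how
#' much smaller the multistate representation is than the expanded
#' single-state network (0 when the multistate syntax buys nothing).
#'
#' @param model the compact `msl_model`.
#' @param flat its expansion ([expand_model()]); computed when `NULL`.
#' @return an object of class `msl_stats` with compact/flat species and
#'   reaction counts and the two reduction fractions.
#' @export
model_stats <- function(model, flat = NULL) {
  if (is.null(flat)) flat <- expand_model(model)
  sc <- length(model$species)
  rc <- length(model$reactions)
  sf <- length(flat$species)
  rf <- length(flat$reactions)
  reduction <- function(compact, flatn) {
    if (flatn == 0) 0 else max(0, 1 - compact / flatn)
  }
  structure(list(species_compact = sc, reactions_compact = rc,
                 species_flat = sf, reactions_flat = rf,
                 species_reduction = reduction(sc, sf),
                 reaction_reduction = reduction(rc, rf)),
            class = "msl_stats")
}

#' @export
print.msl_stats <- function(x, ...) {
  cat(sprintf("species:   %d compact -> %d flat (reduction %.0f%%)\n",
              x$species_compact, x$species_flat, 100 * x$species_reduction))
  cat(sprintf("reactions: %d compact -> %d flat (reduction %.0f%%)\n",
              x$reactions_compact, x$reactions_flat, 100 * x$reaction_reduction))
  invisible(x)
}
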