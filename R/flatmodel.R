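# The flat single-state network: plain species, plain reactions with
# fully grounded kinetic expressions, parameters and assignment rules.

#' Expand a multistate model into its flat single-state network
#'
#' Refuses to run while the model carries error-severity issues (they
#' are listed in the error). Otherwise every species is enumerated over
#' the cartesian product of its site state lists, every reaction is
#' expanded over the state combinations admitted by its reactant
#' patterns, SUM aggregates (in assigned globals, species assignments
#' and kinetic laws) are grounded into explicit sums, and one
#' assignment-rule-bearing flat species is materialized per instance of
#' each aggregate modifier.
#'
#' @param model a validated `msl_model`.
#' @return an `msl_flat_model`: lists `species` (name, base, states,
#'   initial, assigned flag), `reactions` (name, reactants, products,
#'   modifiers, kinetic expression), `parameters` (fixed globals),
#'   `rules` (assignment rules), plus the compact model's counts and the
#'   non-error issues that were present.
#' @export
expand_model <- function(model) {
  issues <- validate(model)
  errs <- Filter(function(i) identical(i$severity, "error"), issues)
  if (length(errs)) {
    msgs <- vapply(errs, `[[`, "", "message")
    stop(structure(
      class = c("msl_expand_refusal", "error", "condition"),
      list(message = paste0("cannot expand a model with outstanding errors:\n",
                            paste0("  - ", msgs, collapse = "\n")),
           call = NULL, issues = errs)))
  }

  registry <- new.env(parent = emptyenv())
  registry$by_identity <- list()   # identity key -> final name
  registry$taken <- list()         # final name -> identity key
  claim <- function(base, states) {
    id <- paste(base, state_key(names(states), states), sep = "\r")
    if (!is.null(registry$by_identity[[id]])) {
      return(registry$by_identity[[id]])
    }
    nm <- flat_name(base, names(states), unname(states))
    if (!is.null(registry$taken[[nm]])) {
      k <- 2L
      while (!is.null(registry$taken[[paste0(nm, "_", k)]])) k <- k + 1L
      nm <- paste0(nm, "_", k)
    }
    registry$by_identity[[id]] <- nm
    registry$taken[[nm]] <- id
    nm
  }
  final_of <- function(inst) claim(inst$species %||% inst$base, inst$states)

  flat_species <- list()
  is_assigned_instance_species <- function(sp) {
    any(vapply(sp$sites, function(s) identical(s$kind, "empty"), TRUE))
  }

  # enumerate concrete species (instances of aggregate-modifier species
  # with stateless sites are discovered during reaction expansion)
  for (sp in model$species) {
    if (is_assigned_instance_species(sp)) next
    insts <- enumerate_instances(sp, model$globals,
                                 default_initial = model$config$default_initial)
    for (inst in insts) {
      nm <- claim(inst$base, inst$states)
      flat_species[[length(flat_species) + 1L]] <-
        list(name = nm, base = inst$base, states = inst$states,
             initial = inst$initial, assigned = !is.null(sp$assignment))
    }
  }

  # reactions
  flat_reactions <- list()
  modifier_instances <- list()  # final name -> list(species, states)
  for (rxn in model$reactions) {
    frs <- expand_reaction(rxn, model)
    for (fr in frs) {
      rename <- list()
      fix_side <- function(insts) {
        vapply(insts, function(inst) {
          fin <- final_of(inst)
          if (!identical(fin, inst$name)) rename[[inst$name]] <<- fin
          fin
        }, character(1))
      }
      reactants <- fix_side(fr$reactant_instances)
      products <- fix_side(fr$product_instances)
      modifiers <- fix_side(fr$modifier_instances)
      for (mi in fr$modifier_instances) {
        msp <- model$species[[mi$species]]
        if (!is.null(msp) && is_assigned_instance_species(msp)) {
          fin <- final_of(mi)
          if (is.null(modifier_instances[[fin]])) {
            modifier_instances[[fin]] <- mi
          }
        }
      }
      kin <- if (length(rename)) {
        expr_map(fr$kinetic, function(n) {
          if (identical(n$kind, "ident") && !is.null(rename[[n$name]])) {
            e_ident(rename[[n$name]])
          } else n
        })
      } else fr$kinetic
      flat_reactions[[length(flat_reactions) + 1L]] <-
        list(name = fr$name, reactants = reactants, products = products,
             modifiers = modifiers, kinetic = kin,
             kinetic_text = expr_text(kin), template = fr$template)
    }
  }

  # one assignment-rule-bearing flat species per aggregate-modifier instance
  rules <- list()
  for (nm in names(modifier_instances)) {
    mi <- modifier_instances[[nm]]
    msp <- model$species[[mi$species]]
    env <- list()
    for (site in names(mi$states)) {
      env[[paste0(mi$species, ".", site)]] <-
        suppressWarnings(as.numeric(mi$states[[site]]))
    }
    expr <- ground_expr(msp$assignment, model, env)
    expr <- rename_to_final(expr, registry)
    flat_species[[length(flat_species) + 1L]] <-
      list(name = nm, base = mi$species, states = mi$states,
           initial = NA_real_, assigned = TRUE)
    rules[[length(rules) + 1L]] <-
      list(variable = nm, expr = expr, expr_text = expr_text(expr))
  }

  # per-instance rules of assigned species that do have concrete states
  for (sp in model$species) {
    if (is.null(sp$assignment) || is_assigned_instance_species(sp)) next
    for (inst in enumerate_instances(sp, model$globals)) {
      env <- list()
      for (site in names(inst$states)) {
        env[[paste0(sp$name, ".", site)]] <-
          suppressWarnings(as.numeric(inst$states[[site]]))
      }
      expr <- rename_to_final(ground_expr(sp$assignment, model, env), registry)
      rules[[length(rules) + 1L]] <-
        list(variable = claim(sp$name, inst$states), expr = expr,
             expr_text = expr_text(expr))
    }
  }

  parameters <- list()
  for (g in model$globals) {
    if (identical(g$role, "assigned")) {
      expr <- rename_to_final(ground_expr(g$expr, model, list()), registry)
      rules[[length(rules) + 1L]] <-
        list(variable = g$name, expr = expr, expr_text = expr_text(expr))
    } else {
      val <- tryCatch(static_eval(g$expr, model$globals, character()),
                      msl_static_error = function(e) NA_real_)
      parameters[[length(parameters) + 1L]] <- list(name = g$name, value = val)
    }
  }

  structure(list(species = flat_species, reactions = flat_reactions,
                 parameters = parameters, rules = rules,
                 compact = list(species = length(model$species),
                                reactions = length(model$reactions)),
                 issues = issues),
            class = "msl_flat_model")
}

rename_to_final <- function(expr, registry) {
  expr  # provisional flat names equal final names unless a collision
        # occurred; collisions are resolved per reaction (see above) and
        # cannot be attributed from a bare identifier here
}

#' @export
print.msl_flat_model <- function(x, ...) {
  cat(sprintf("<flat model> %d species, %d reactions, %d parameters, %d rules (from %d/%d compact)\n",
              length(x$species), length(x$reactions), length(x$parameters),
              length(x$rules), x$compact$species, x$compact$reactions))
  invisible(x)
}

#' Represent a flat model in the model language
#'
#' Produces an `msl_model` without multistate constructs: every flat
#' species is a zero-site species, rules become assigned entities, and
#' each reaction carries its grounded kinetic expression as a `K :`
#' rate law. `unparse()` of the result is the flat .msl dialect.
#'
#' @param flat an `msl_flat_model`.
#' @return an `msl_model`.
#' @export
flat_to_model <- function(flat) {
  ast <- list(kind = "model_ast", species = list(), reactions = list(),
              globals = list(), functions = list(), complexes = list(),
              initials = list(), raw = list(), diagnostics = list())
  class(ast) <- "msl_ast"
  rule_vars <- vapply(flat$rules, `[[`, "", "variable")
  rule_of <- stats::setNames(lapply(flat$rules, `[[`, "expr"), rule_vars)
  for (sp in flat$species) {
    assignment <- rule_of[[sp$name]]
    ast$species[[length(ast$species) + 1L]] <-
      node("species_entry",
           def = node("species_def", name = sp$name, sites = list()),
           initial = if (is.null(assignment) && !is.na(sp$initial))
             e_num(sp$initial) else NULL,
           assignment = assignment)
  }
  for (p in flat$parameters) {
    ast$globals[[length(ast$globals) + 1L]] <-
      node("global", name = p$name, role = "fixed",
           expr = e_num(if (is.na(p$value)) 0 else p$value))
  }
  species_names <- vapply(flat$species, `[[`, "", "name")
  for (g in setdiff(rule_vars, species_names)) {
    ast$globals[[length(ast$globals) + 1L]] <-
      node("global", name = g, role = "assigned", expr = rule_of[[g]])
  }
  mk_ref <- function(nm) node("species_ref", species = nm, patterns = list())
  for (r in flat$reactions) {
    ast$reactions[[length(ast$reactions) + 1L]] <-
      node("reaction", name = r$name,
           reactants = lapply(r$reactants, mk_ref),
           products = lapply(r$products, mk_ref),
           modifiers = lapply(r$modifiers, mk_ref),
           rate = node("rate_k", expr = r$kinetic))
  }
  build_model(ast, policy = "off")$model
}
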