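# Expansion of a multistate model into the equivalent flat single-state
# network. One multistate reaction becomes one flat reaction per
# combination of states admitted by its reactant patterns; succ/pred and
# transfer-of-state are resolved per combination; SUM aggregates are
# grounded into explicit sums of flat species; rate laws are
# instantiated with SITE parameters bound to numeric state values.
# The whole pipeline is deterministic: identical input gives
# byte-identical output.

#' Deterministic flat name for a species instance
#'
#' `base` for a zero-site species, otherwise
#' `base_site1state1_site2state2...` in site declaration order; label
#' characters outside `[A-Za-z0-9_]` are replaced by `_`.
#'
#' @param base species name.
#' @param site_names,labels character vectors of equal length.
#' @return a single string.
#' @keywords internal
flat_name <- function(base, site_names, labels) {
  if (length(site_names) == 0) return(base)
  parts <- gsub("[^A-Za-z0-9_]", "_", paste0(site_names, labels))
  paste(c(base, parts), collapse = "_")
}

#' Enumerate the flat instances of a multistate species
#'
#' Cartesian product over the sites in declaration order, the last site
#' varying fastest. Initial amounts come from the per-state overrides
#' where present, else from the species default.
#'
#' @param species a species entry of an `msl_model`.
#' @param globals fixed global quantities used to resolve symbolic
#'   ranges.
#' @param default_initial fallback initial amount.
#' @return list of instances: `list(name, base, states, initial)` with
#'   `states` a named character vector (site -> label).
#' @export
enumerate_instances <- function(species, globals = list(), default_initial = 0) {
  site_names <- vapply(species$sites, `[[`, "", "name")
  statelists <- lapply(species$sites, resolve_state_list, globals = globals)
  grids <- lapply(statelists, `[[`, "labels")
  combos <- cartesian_last_fastest(grids)
  default <- species$default_initial
  default_val <- if (is.null(default)) default_initial else
    tryCatch(static_eval(default, normalize_globals(globals), character()),
             msl_static_error = function(e) NA_real_)
  lapply(combos, function(labels) {
    key <- state_key(site_names, labels)
    init <- if (!is.null(species$per_state[[key]])) {
      tryCatch(static_eval(species$per_state[[key]], normalize_globals(globals),
                           character()),
               msl_static_error = function(e) NA_real_)
    } else default_val
    list(name = flat_name(species$name, site_names, labels),
         base = species$name,
         states = stats::setNames(as.character(labels), site_names),
         initial = init)
  })
}

# all combinations of one element per grid; last grid varies fastest;
# zero grids -> one empty combination; any empty grid -> none
cartesian_last_fastest <- function(grids) {
  if (length(grids) == 0) return(list(character()))
  if (any(vapply(grids, length, 1L) == 0)) return(list())
  idx <- do.call(expand.grid, c(rev(lapply(grids, seq_along)),
                                list(KEEP.OUT.ATTRS = FALSE)))
  idx <- idx[, rev(seq_along(grids)), drop = FALSE]
  lapply(seq_len(nrow(idx)), function(r) {
    vapply(seq_along(grids), function(j) grids[[j]][[idx[r, j]]], character(1))
  })
}

# ------------------------------------------------------------- expansion env

# Mutable context shared across one expand_model() run.
expansion_env <- function(model) {
  env <- new.env(parent = emptyenv())
  env$model <- model
  env$statelists <- list()
  env$warnings <- list()
  env$get_states <- function(sp_name, site_name) {
    key <- sl_key(sp_name, site_name)
    if (is.null(env$statelists[[key]])) {
      env$statelists[[key]] <-
        resolve_state_list(get_site(model, sp_name, site_name), model$globals)
    }
    env$statelists[[key]]
  }
  env
}

model_statelist <- function(model, sp_name, site_name) {
  site <- get_site(model, sp_name, site_name)
  if (is.null(site)) {
    stop(sprintf("species '%s' has no site '%s'", sp_name, site_name),
         call. = FALSE)
  }
  resolve_state_list(site, model$globals)
}

# ------------------------------------------------------------ expand a rule

#' Expand one multistate reaction
#'
#' Emits one flat reaction per combination of states admitted by the
#' reactant patterns (unconstrained sites of a multistate reactant
#' iterate over their full state lists). Product and modifier patterns
#' resolve per combination: fixed states verbatim, unmentioned sites of
#' a species that also appears as a reactant carry their state through,
#' `succ`/`pred` step along the site's declaration order, and transfer
#' of state copies (optionally through an operator) the matched state of
#' the named reactant.
#'
#' @param rxn a reaction node (validated).
#' @param model the containing `msl_model`.
#' @return list of flat reactions: `list(name, reactants, products,
#'   modifiers, modifier_instances, kinetic, kinetic_text)`; the name
#'   lists are flat species names with stoichiometry by repetition.
#' @export
expand_reaction <- function(rxn, model) {
  # dimensions: one per (reactant occurrence, site)
  dims <- list()
  for (i in seq_along(rxn$reactants)) {
    ref <- rxn$reactants[[i]]
    sp <- model$species[[ref$species]]
    if (is.null(sp)) {
      stop(sprintf("reaction '%s' references undefined species '%s'",
                   rxn$name, ref$species), call. = FALSE)
    }
    for (site in site_names_of(sp)) {
      states <- model_statelist(model, ref$species, site)
      if (identical(get_site(model, ref$species, site)$kind, "empty")) next
      admitted <- pattern_admitted(ref$patterns[[site]], states, model$globals)
      dims[[length(dims) + 1L]] <- list(occ = i, site = site,
                                        labels = admitted, states = states)
    }
  }
  combos <- cartesian_last_fastest(lapply(dims, `[[`, "labels"))
  out <- vector("list", length(combos))
  for (k in seq_along(combos)) {
    combo <- combos[[k]]
    # matched states per reactant occurrence
    occ_states <- lapply(rxn$reactants, function(ref) {
      sp <- model$species[[ref$species]]
      stats::setNames(character(0), character(0))
    })
    for (j in seq_along(dims)) {
      d <- dims[[j]]
      occ_states[[d$occ]][[d$site]] <- combo[[j]]
    }
    reactant_insts <- lapply(seq_along(rxn$reactants), function(i) {
      ref <- rxn$reactants[[i]]
      st <- occ_states[[i]]
      list(species = ref$species,
           states = st,
           name = flat_name(ref$species, names(st), unname(st)))
    })
    resolve_output <- function(ref) {
      sp <- model$species[[ref$species]]
      st <- character(0)
      for (site_name in site_names_of(sp)) {
        site_def <- get_site(model, ref$species, site_name)
        pat <- ref$patterns[[site_name]]
        if ((is.null(pat) || identical(pat$kind, "any")) &&
            identical(site_def$kind, "empty")) next
        label <- resolve_output_site(ref, site_name, pat, model,
                                     rxn, reactant_insts)
        st[[site_name]] <- label
      }
      list(species = ref$species, states = st,
           name = flat_name(ref$species, names(st), unname(st)))
    }
    product_insts <- lapply(rxn$products, resolve_output)
    modifier_insts <- lapply(rxn$modifiers, resolve_output)
    kin <- instantiate_rate_law(
      list(reactants = reactant_insts, modifiers = modifier_insts),
      rxn$rate, model)
    out[[k]] <- list(
      name = if (length(combos) == 1L) rxn$name else paste0(rxn$name, "_", k),
      reactants = vapply(reactant_insts, `[[`, "", "name"),
      products = vapply(product_insts, `[[`, "", "name"),
      modifiers = vapply(modifier_insts, `[[`, "", "name"),
      reactant_instances = reactant_insts,
      product_instances = product_insts,
      modifier_instances = modifier_insts,
      kinetic = kin,
      kinetic_text = expr_text(kin),
      template = rxn$name)
  }
  out
}

resolve_output_site <- function(ref, site_name, pat, model, rxn, reactant_insts) {
  source_state <- function(species, site) {
    for (inst in reactant_insts) {
      if (identical(inst$species, species)) {
        if (!site %in% names(inst$states)) {
          stop(sprintf("reaction '%s': reactant '%s' has no matched state for site '%s'",
                       rxn$name, species, site), call. = FALSE)
        }
        return(inst$states[[site]])
      }
    }
    stop(sprintf("reaction '%s': no reactant '%s' to source a state from",
                 rxn$name, species), call. = FALSE)
  }
  if (is.null(pat) || identical(pat$kind, "any")) {
    states <- model_statelist(model, ref$species, site_name)
    if (length(states$labels) == 1L &&
        !any(vapply(rxn$reactants, function(r) identical(r$species, ref$species), TRUE))) {
      return(states$labels[[1]])
    }
    return(source_state(ref$species, site_name))
  }
  switch(pat$kind,
    fixed = pat$label,
    opcall = {
      states <- model_statelist(model, ref$species, pat$site)
      apply_state_op(states, source_state(ref$species, pat$site), pat$op)
    },
    transfer = {
      src_states <- model_statelist(model, pat$src_species, pat$src_site)
      label <- apply_state_op(src_states,
                              source_state(pat$src_species, pat$src_site),
                              pat$op)
      target <- model_statelist(model, ref$species, site_name)
      if (length(target$labels) > 0 && !label %in% target$labels) {
        stop(sprintf("reaction '%s': transferred state '%s' is not a state of %s.%s",
                     rxn$name, label, ref$species, site_name), call. = FALSE)
      }
      label
    },
    stop(sprintf("reaction '%s': pattern of kind '%s' cannot appear in a product or modifier",
                 rxn$name, pat$kind), call. = FALSE))
}

# ------------------------------------------------------------- rate laws

#' Instantiate a rate law for one flat reaction
#'
#' Mass action multiplies the rate constant by the flat reactant names
#' (stoichiometry by repetition). A user-defined law substitutes the
#' function body: GLQ arguments stay as global references, SUB arguments
#' bind to the matched flat instance of the named species, and SITE
#' arguments bind to the numeric state value of the referenced site in
#' this instance (an error if that state label is not an integer). The
#' `K :` form takes the written expression verbatim. Any SUM aggregate
#' in the result is grounded against the instance context.
#'
#' @param ctx `list(reactants=, modifiers=)` of flat instances as built
#'   by [expand_reaction()].
#' @param rate a rate node (`rate_ma`, `rate_ud`, `rate_k` or `NULL`,
#'   which falls back to mass action with rate 1).
#' @param model the containing model.
#' @return a grounded kinetic expression AST.
#' @export
instantiate_rate_law <- function(ctx, rate, model) {
  env <- instance_accessor_env(ctx)
  if (is.null(rate)) rate <- node("rate_ma", rate = e_num(1))
  expr <- switch(rate$kind,
    rate_ma = {
      acc <- rate$rate
      for (inst in ctx$reactants) acc <- e_binop("*", acc, e_ident(inst$name))
      acc
    },
    rate_k = rate$expr,
    rate_ud = {
      f <- model$functions[[rate$call$fn]]
      if (is.null(f)) {
        stop(sprintf("rate law calls undefined function '%s'", rate$call$fn),
             call. = FALSE)
      }
      if (length(rate$call$args) != length(f$params)) {
        stop(sprintf("'%s' expects %d argument(s), got %d", rate$call$fn,
                     length(f$params), length(rate$call$args)), call. = FALSE)
      }
      bindings <- list()
      for (i in seq_along(f$params)) {
        p <- f$params[[i]]
        a <- rate$call$args[[i]]
        bindings[[p$name]] <- switch(p$role,
          GLQ = a,
          SUB = {
            inst <- find_instance(ctx, a$name)
            if (is.null(inst)) {
              stop(sprintf("SUB argument '%s' does not match a reactant or modifier",
                           a$name), call. = FALSE)
            }
            e_ident(inst$name)
          },
          SITE = {
            key <- paste0(a$species, ".", a$site)
            val <- env[[key]]
            if (is.null(val)) {
              stop(sprintf("SITE argument '%s' does not match a reactant or modifier site",
                           key), call. = FALSE)
            }
            if (is.na(val) || val != round(val)) {
              stop(sprintf("SITE argument '%s' is bound to a non-integer state label; a numeric binding is impossible",
                           key), call. = FALSE)
            }
            e_num(val)
          })
      }
      substitute_idents(f$body, bindings)
    },
    stop("unknown rate kind: ", rate$kind))
  ground_expr(expr, model, env)
}

# "Species.site" -> numeric state value for every instance in ctx;
# non-integer labels are omitted (an access then fails with a clear error)
instance_accessor_env <- function(ctx) {
  env <- list()
  for (inst in c(ctx$reactants, ctx$modifiers)) {
    for (site in names(inst$states)) {
      key <- paste0(inst$species, ".", site)
      if (!is.null(env[[key]])) next
      val <- suppressWarnings(as.numeric(inst$states[[site]]))
      if (!is.na(val)) env[[key]] <- val
      else env[[key]] <- NA_real_
    }
  }
  env
}

find_instance <- function(ctx, species) {
  for (inst in c(ctx$reactants, ctx$modifiers)) {
    if (identical(inst$species, species)) return(inst)
  }
  NULL
}

substitute_idents <- function(expr, bindings) {
  expr_map(expr, function(n) {
    if (identical(n$kind, "ident") && !is.null(bindings[[n$name]])) {
      bindings[[n$name]]
    } else n
  })
}

# Ground SUM aggregates and instance accessors; the result contains only
# numbers, flat names and global names.
ground_expr <- function(expr, model, env = list()) {
  expr_map(expr, function(n) {
    if (identical(n$kind, "sum")) {
      expand_sum(n, model, env)
    } else if (identical(n$kind, "accessor")) {
      key <- paste0(n$species, ".", n$site)
      val <- env[[key]]
      if (is.null(val)) {
        stop(sprintf("site accessor '%s' cannot be resolved in this context", key),
             call. = FALSE)
      }
      if (is.na(val)) {
        stop(sprintf("site accessor '%s' refers to a non-integer state label", key),
             call. = FALSE)
      }
      e_num(val)
    } else n
  })
}

#' Ground a SUM aggregate into an explicit sum of flat species
#'
#' Restricted sites keep the states admitted by the restriction (integer
#' ranges are intersected with the state list, so a window sliding past
#' the end of a chain is truncated rather than an error); unrestricted
#' sites range over their full state lists. With a weight expression,
#' each term is multiplied by the weight with the summed species' site
#' accessors replaced by the term's numeric state values.
#'
#' @param sum_node a `sum` expression node.
#' @param model the containing model.
#' @param env named list mapping `"Species.site"` accessor strings to
#'   numeric values of the enclosing instance (for moving windows such
#'   as a ribosome footprint).
#' @return an expression AST: the explicit sum (an error if no state is
#'   admitted).
#' @export
expand_sum <- function(sum_node, model, env = list()) {
  sp <- model$species[[sum_node$species]]
  if (is.null(sp)) {
    stop(sprintf("SUM over undefined species '%s'", sum_node$species),
         call. = FALSE)
  }
  site_names <- site_names_of(sp)
  restr <- stats::setNames(sum_node$restr,
                           vapply(sum_node$restr, `[[`, "", "site"))
  grids <- lapply(seq_along(sp$sites), function(i) {
    states <- model_statelist(model, sp$name, site_names[[i]])
    r <- restr[[site_names[[i]]]]
    if (is.null(r)) return(states$labels)
    if (identical(r$kind, "enumset")) {
      bad <- setdiff(r$labels, states$labels)
      if (length(bad)) {
        stop(sprintf("SUM restriction state '%s' is not a state of %s.%s",
                     bad[[1]], sp$name, site_names[[i]]), call. = FALSE)
      }
      return(states$labels[states$labels %in% r$labels])
    }
    # integer range, possibly instance-dependent bounds
    lo <- static_eval(subst_env(r$lo, env), model$globals, character())
    hi <- static_eval(subst_env(r$hi, env), model$globals, character())
    if (!states$numeric) {
      stop(sprintf("numeric SUM range on non-numeric states of %s.%s",
                   sp$name, site_names[[i]]), call. = FALSE)
    }
    states$labels[states$values >= lo & states$values <= hi]
  })
  if (any(vapply(grids, length, 1L) == 0)) {
    stop(sprintf("SUM over '%s' selects no state", sp$name), call. = FALSE)
  }
  combos <- cartesian_last_fastest(grids)
  terms <- lapply(combos, function(labels) {
    term <- e_ident(flat_name(sp$name, site_names, labels))
    if (!is.null(sum_node$weight)) {
      wenv <- env
      for (i in seq_along(site_names)) {
        val <- suppressWarnings(as.numeric(labels[[i]]))
        wenv[[paste0(sp$name, ".", site_names[[i]])]] <- val
      }
      w <- ground_expr(sum_node$weight, model, wenv)
      term <- e_binop("*", w, term)
    }
    term
  })
  Reduce(function(a, b) e_binop("+", a, b), terms)
}

subst_env <- function(expr, env) {
  if (length(env) == 0) return(expr)
  expr_map(expr, function(n) {
    if (identical(n$kind, "accessor")) {
      key <- paste0(n$species, ".", n$site)
      if (!is.null(env[[key]]) && !is.na(env[[key]])) return(e_num(env[[key]]))
    }
    n
  })
}
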