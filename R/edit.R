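# Rename and delete with user-selectable policies. Renames propagate to
# every reference; deletes offer, per class of reference, the choice of
# cascading, substituting a numeric value, or deliberately leaving the
# inconsistency (validate() then reports each dangling reference).

rename_in_expr <- function(expr, old, new) {
  expr_map(expr, function(n) {
    if (identical(n$kind, "ident") && identical(n$name, old)) {
      n$name <- new
    } else if (identical(n$kind, "accessor") && identical(n$species, old)) {
      n$species <- new
    } else if (identical(n$kind, "sum") && identical(n$species, old)) {
      n$species <- new
    } else if (identical(n$kind, "call") && identical(n$fn, old)) {
      n$fn <- new
    }
    n
  })
}

rename_in_ref <- function(ref, old, new) {
  if (identical(ref$species, old)) ref$species <- new
  ref$patterns <- lapply(ref$patterns, function(pat) {
    if (identical(pat$kind, "transfer") && identical(pat$src_species, old)) {
      pat$src_species <- new
    }
    if (identical(pat$kind, "range")) {
      pat$lo <- rename_in_expr(pat$lo, old, new)
      pat$hi <- rename_in_expr(pat$hi, old, new)
    }
    pat
  })
  ref
}

rename_list_key <- function(lst, old, new) {
  names(lst)[names(lst) == old] <- new
  lst
}

# core: rename one entity name across the whole model (no checks)
rename_everywhere <- function(model, old, new) {
  model$species <- rename_list_key(model$species, old, new)
  model$species <- lapply(model$species, function(sp) {
    if (identical(sp$name, old)) sp$name <- new
    if (!is.null(sp$complex_of)) {
      sp$complex_of[sp$complex_of == old] <- new
    }
    if (identical(sp$generated_by, old)) sp$generated_by <- new
    sp$sites <- lapply(sp$sites, function(s) {
      if (!is.null(s$tracks) && identical(s$tracks[[1]], old)) s$tracks[[1]] <- new
      if (identical(s$kind, "range")) {
        s$lo <- rename_in_expr(s$lo, old, new)
        s$hi <- rename_in_expr(s$hi, old, new)
      }
      s
    })
    if (!is.null(sp$default_initial)) {
      sp$default_initial <- rename_in_expr(sp$default_initial, old, new)
    }
    if (!is.null(sp$assignment)) {
      sp$assignment <- rename_in_expr(sp$assignment, old, new)
    }
    sp$per_state <- lapply(sp$per_state, rename_in_expr, old = old, new = new)
    sp
  })
  model$globals <- rename_list_key(model$globals, old, new)
  model$globals <- lapply(model$globals, function(g) {
    if (identical(g$name, old)) g$name <- new
    if (identical(g$generated_by, old)) g$generated_by <- new
    g$expr <- rename_in_expr(g$expr, old, new)
    g
  })
  model$functions <- rename_list_key(model$functions, old, new)
  model$functions <- lapply(model$functions, function(f) {
    if (identical(f$name, old)) f$name <- new
    # bodies reference parameters; only nested calls can name the entity
    f$body <- expr_map(f$body, function(n) {
      if (identical(n$kind, "call") && identical(n$fn, old)) n$fn <- new
      n
    })
    f
  })
  model$reactions <- lapply(model$reactions, function(r) {
    r$reactants <- lapply(r$reactants, rename_in_ref, old = old, new = new)
    r$products <- lapply(r$products, rename_in_ref, old = old, new = new)
    r$modifiers <- lapply(r$modifiers, rename_in_ref, old = old, new = new)
    if (!is.null(r$rate)) {
      if (identical(r$rate$kind, "rate_ma")) {
        r$rate$rate <- rename_in_expr(r$rate$rate, old, new)
      } else if (identical(r$rate$kind, "rate_ud")) {
        r$rate$call <- rename_in_expr(r$rate$call, old, new)
      } else if (identical(r$rate$kind, "rate_k")) {
        r$rate$expr <- rename_in_expr(r$rate$expr, old, new)
      }
    }
    if (identical(r$generated_by, old)) r$generated_by <- new
    r
  })
  model$complexes <- rename_list_key(model$complexes, old, new)
  model$complexes <- lapply(model$complexes, function(cx) {
    if (identical(cx$name, old)) cx$name <- new
    cx$components <- lapply(cx$components, rename_in_ref, old = old, new = new)
    cx
  })
  model
}

entity_kind <- function(model, name) {
  if (!is.null(model$species[[name]])) "species"
  else if (!is.null(model$globals[[name]])) "global"
  else if (!is.null(model$functions[[name]])) "function"
  else if (!is.null(model$complexes[[name]])) "complex"
  else if (!is.null(model$reactions[[name]])) "reaction"
  else NA_character_
}

#' Rename a model entity
#'
#' Renames a species, global quantity, function, complex or reaction and
#' propagates the change to every reference: reaction participants,
#' transfer sources, SUM aggregates, site accessors, range bounds,
#' complex components and per-state initials. Auto-named complexes
#' containing a renamed component regenerate their name (and that
#' rename propagates in turn).
#'
#' @param model an `msl_model`.
#' @param old_name existing entity name.
#' @param new_name new name; must be a legal identifier not in use.
#' @return the updated model. A name collision is an error and leaves
#'   the model unchanged.
#' @export
rename_entity <- function(model, old_name, new_name) {
  if (identical(old_name, new_name)) return(model)
  kind <- entity_kind(model, old_name)
  if (is.na(kind)) stop("no entity named '", old_name, "'")
  if (!is_valid_ident(new_name)) {
    stop("'", new_name, "' is not a legal identifier")
  }
  if (!is.na(entity_kind(model, new_name))) {
    stop("cannot rename '", old_name, "' to '", new_name,
         "': the name is already in use")
  }
  if (identical(kind, "reaction")) {
    model$reactions <- rename_list_key(model$reactions, old_name, new_name)
    model$reactions[[new_name]]$name <- new_name
    return(model)
  }
  model <- rename_everywhere(model, old_name, new_name)
  # regenerate the names of auto-named complexes built from renamed parts
  repeat {
    changed <- FALSE
    for (cx in model$complexes) {
      if (!isTRUE(cx$auto_name)) next
      auto <- paste(vapply(cx$components, `[[`, "", "species"), collapse = "_")
      if (!identical(auto, cx$name) && is.na(entity_kind(model, auto))) {
        old_cx <- cx$name
        model <- rename_everywhere(model, old_cx, auto)
        for (suffix in c("_bind", "_unbind", "_kon", "_koff")) {
          model <- rename_everywhere(model, paste0(old_cx, suffix),
                                     paste0(auto, suffix))
          model$reactions <- rename_list_key(model$reactions,
                                             paste0(old_cx, suffix),
                                             paste0(auto, suffix))
        }
        for (rn in names(model$reactions)) {
          model$reactions[[rn]]$name <- rn
        }
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  model
}

#' Rename a site of a multistate species
#'
#' Propagates to every reaction pattern, operator argument, transfer
#' source, site accessor, SUM restriction and per-state initial key that
#' references the site of that species.
#'
#' @param model an `msl_model`.
#' @param species the species whose site is renamed.
#' @param old_site,new_site site names.
#' @return the updated model.
#' @export
rename_site <- function(model, species, old_site, new_site) {
  sp <- model$species[[species]]
  if (is.null(sp)) stop("no species named '", species, "'")
  snames <- site_names_of(sp)
  if (!old_site %in% snames) {
    stop("species '", species, "' has no site '", old_site, "'")
  }
  if (new_site %in% snames) {
    stop("species '", species, "' already has a site '", new_site, "'")
  }
  if (!is_valid_ident(new_site)) stop("'", new_site, "' is not a legal identifier")
  fix_expr <- function(expr) {
    expr_map(expr, function(n) {
      if (identical(n$kind, "accessor") && identical(n$species, species) &&
          identical(n$site, old_site)) {
        n$site <- new_site
      } else if (identical(n$kind, "sum") && identical(n$species, species)) {
        n$restr <- lapply(n$restr, function(r) {
          if (identical(r$site, old_site)) r$site <- new_site
          r
        })
      }
      n
    })
  }
  fix_ref <- function(ref) {
    ref$patterns <- lapply(ref$patterns, function(pat) {
      if (identical(pat$kind, "opcall") && identical(ref$species, species) &&
          identical(pat$site, old_site)) {
        pat$site <- new_site
      }
      if (identical(pat$kind, "transfer") &&
          identical(pat$src_species, species) &&
          identical(pat$src_site, old_site)) {
        pat$src_site <- new_site
      }
      pat
    })
    if (identical(ref$species, species)) {
      ref$patterns <- rename_list_key(ref$patterns, old_site, new_site)
    }
    ref
  }
  model$species[[species]]$sites <- lapply(sp$sites, function(s) {
    if (identical(s$name, old_site)) s$name <- new_site
    s
  })
  model$species[[species]]$per_state <-
    stats::setNames(sp$per_state,
                    vapply(names(sp$per_state), function(key) {
                      gsub(paste0("(^|,)", old_site, "="),
                           paste0("\\1", new_site, "="), key)
                    }, ""))
  for (nm in names(model$species)) {
    spx <- model$species[[nm]]
    if (!is.null(spx$assignment)) {
      model$species[[nm]]$assignment <- fix_expr(spx$assignment)
    }
    model$species[[nm]]$sites <- lapply(spx$sites, function(s) {
      if (!is.null(s$tracks) && identical(s$tracks[[1]], species) &&
          identical(s$tracks[[2]], old_site)) {
        s$tracks[[2]] <- new_site
      }
      s
    })
  }
  model$globals <- lapply(model$globals, function(g) {
    g$expr <- fix_expr(g$expr)
    g
  })
  model$reactions <- lapply(model$reactions, function(r) {
    r$reactants <- lapply(r$reactants, fix_ref)
    r$products <- lapply(r$products, fix_ref)
    r$modifiers <- lapply(r$modifiers, fix_ref)
    if (!is.null(r$rate)) {
      if (identical(r$rate$kind, "rate_ma")) r$rate$rate <- fix_expr(r$rate$rate)
      else if (identical(r$rate$kind, "rate_ud")) r$rate$call <- fix_expr(r$rate$call)
      else if (identical(r$rate$kind, "rate_k")) r$rate$expr <- fix_expr(r$rate$expr)
    }
    r
  })
  model$complexes <- lapply(model$complexes, function(cx) {
    cx$components <- lapply(cx$components, fix_ref)
    cx
  })
  model
}

# ---------------------------------------------------------------- deletion

expr_references <- function(expr, name) {
  found <- FALSE
  if (is.null(expr)) return(FALSE)
  expr_walk(expr, function(n) {
    if ((identical(n$kind, "ident") && identical(n$name, name)) ||
        (identical(n$kind, "accessor") && identical(n$species, name)) ||
        (identical(n$kind, "sum") && identical(n$species, name)) ||
        (identical(n$kind, "call") && identical(n$fn, name))) {
      found <<- TRUE
    }
  })
  found
}

replace_in_expr <- function(expr, name, value) {
  expr_map(expr, function(n) {
    if ((identical(n$kind, "ident") && identical(n$name, name)) ||
        (identical(n$kind, "accessor") && identical(n$species, name)) ||
        (identical(n$kind, "sum") && identical(n$species, name))) {
      e_num(value)
    } else n
  })
}

reaction_rate_expr <- function(r) {
  if (is.null(r$rate)) return(NULL)
  switch(r$rate$kind, rate_ma = r$rate$rate, rate_ud = r$rate$call,
         rate_k = r$rate$expr)
}

reaction_references <- function(r, name) {
  refs <- c(r$reactants, r$products, r$modifiers)
  in_refs <- any(vapply(refs, function(ref) {
    identical(ref$species, name) ||
      any(vapply(ref$patterns, function(p) {
        identical(p$kind, "transfer") && identical(p$src_species, name)
      }, TRUE))
  }, TRUE))
  in_rate <- expr_references(reaction_rate_expr(r), name)
  list(participant = in_refs, rate = in_rate)
}

#' Delete a model entity under a chosen policy
#'
#' References to the deleted entity are handled per reference class:
#'
#' * reactions that use the entity: `"cascade"` removes the reaction;
#'   `"replace"` substitutes `value` where the entity occurs only in
#'   the kinetic expression (a number cannot stand in as a reaction
#'   participant -- that case falls back to leaving the inconsistency,
#'   with an issue saying so); `"leave"` keeps the reaction and records
#'   an error issue per dangling reference.
#' * expressions (global quantities, species assignments and initials):
#'   `"cascade"` deletes the referencing entity, `"replace"`
#'   substitutes `value`, `"leave"` keeps the dangling reference with
#'   an error issue.
#' * complexes containing the entity as a component: `"cascade"`
#'   removes the complex with its generated species/reactions,
#'   otherwise the complex is kept and an issue recorded.
#'
#' The model is returned in all cases; a model left with dangling
#' references remains saveable and [validate()] keeps reporting them.
#'
#' @param model an `msl_model`.
#' @param name entity to delete (species, global, function, reaction or
#'   complex).
#' @param policy a single policy for all classes, or a named character
#'   vector with any of the keys `reactions`, `expressions`,
#'   `complexes`, e.g. `c(reactions = "cascade", expressions = "leave")`.
#'   Policies: `"cascade"`, `"replace"`, `"leave"`.
#' @param value the numeric replacement used by `"replace"`.
#' @return list with elements `model` and `issues`.
#' @export
delete_entity <- function(model, name, policy = NULL, value = NULL) {
  kind <- entity_kind(model, name)
  if (is.na(kind)) stop("no entity named '", name, "'")
  default <- model$config$default_delete %||% "cascade"
  pol <- c(reactions = default, expressions = default, complexes = default)
  if (!is.null(policy)) {
    if (is.null(names(policy)) || all(names(policy) == "")) {
      pol[] <- policy[[1]]
    } else {
      pol[names(policy)] <- policy
    }
  }
  stopifnot(all(pol %in% c("cascade", "replace", "leave")))
  if (any(pol == "replace") && is.null(value)) {
    stop("policy 'replace' requires a numeric 'value'")
  }
  ic <- issue_collector()

  if (kind == "reaction") {
    model$reactions[[name]] <- NULL
    return(list(model = model, issues = ic$issues))
  }
  if (kind == "complex") {
    model <- drop_complex(model, name)
    return(list(model = model, issues = ic$issues))
  }

  # reactions
  for (rn in names(model$reactions)) {
    r <- model$reactions[[rn]]
    hit <- reaction_references(r, name)
    if (!hit$participant && !hit$rate) next
    if (pol[["reactions"]] == "cascade") {
      model$reactions[[rn]] <- NULL
    } else if (pol[["reactions"]] == "replace") {
      if (hit$participant) {
        ic$add("error", "dangling_ref",
               sprintf("reaction '%s': a numeric value cannot replace '%s' as a reaction participant; the inconsistency is left in place",
                       rn, name))
      } else {
        rate <- r$rate
        if (identical(rate$kind, "rate_ma")) {
          rate$rate <- replace_in_expr(rate$rate, name, value)
        } else if (identical(rate$kind, "rate_ud")) {
          rate$call <- replace_in_expr(rate$call, name, value)
        } else {
          rate$expr <- replace_in_expr(rate$expr, name, value)
        }
        model$reactions[[rn]]$rate <- rate
      }
    } else {
      ic$add("error", "dangling_ref",
             sprintf("reaction '%s' still references deleted entity '%s'", rn, name))
    }
  }

  # expressions of globals
  for (gn in names(model$globals)) {
    if (identical(gn, name)) next
    g <- model$globals[[gn]]
    if (!expr_references(g$expr, name)) next
    if (pol[["expressions"]] == "cascade") {
      model$globals[[gn]] <- NULL
    } else if (pol[["expressions"]] == "replace") {
      model$globals[[gn]]$expr <- replace_in_expr(g$expr, name, value)
    } else {
      ic$add("error", "dangling_ref",
             sprintf("expression of global quantity '%s' still references deleted entity '%s'",
                     gn, name))
    }
  }

  # expressions of species (assignments, initials)
  for (sn in names(model$species)) {
    if (identical(sn, name)) next
    sp <- model$species[[sn]]
    exprs <- c(list(assignment = sp$assignment, default = sp$default_initial),
               sp$per_state)
    if (!any(vapply(exprs, expr_references, TRUE, name = name))) next
    if (pol[["expressions"]] == "cascade") {
      model$species[[sn]] <- NULL
    } else if (pol[["expressions"]] == "replace") {
      if (!is.null(sp$assignment)) {
        model$species[[sn]]$assignment <- replace_in_expr(sp$assignment, name, value)
      }
      if (!is.null(sp$default_initial)) {
        model$species[[sn]]$default_initial <-
          replace_in_expr(sp$default_initial, name, value)
      }
      model$species[[sn]]$per_state <-
        lapply(sp$per_state, replace_in_expr, name = name, value = value)
    } else {
      ic$add("error", "dangling_ref",
             sprintf("expression of species '%s' still references deleted entity '%s'",
                     sn, name))
    }
  }

  # complexes with the entity as a component
  for (cn in names(model$complexes)) {
    cx <- model$complexes[[cn]]
    if (!any(vapply(cx$components, function(cp) identical(cp$species, name), TRUE))) next
    if (pol[["complexes"]] == "cascade") {
      model <- drop_complex(model, cn)
    } else {
      ic$add("error", "dangling_ref",
             sprintf("complex '%s' still contains deleted component '%s'", cn, name))
    }
  }

  switch(kind,
    species = { model$species[[name]] <- NULL },
    global = { model$globals[[name]] <- NULL },
    "function" = { model$functions[[name]] <- NULL })
  list(model = model, issues = ic$issues)
}

drop_complex <- function(model, name) {
  model$complexes[[name]] <- NULL
  for (sn in names(model$species)) {
    if (identical(model$species[[sn]]$generated_by, name)) {
      model$species[[sn]] <- NULL
    }
  }
  for (rn in names(model$reactions)) {
    if (identical(model$reactions[[rn]]$generated_by, name)) {
      model$reactions[[rn]] <- NULL
    }
  }
  for (gn in names(model$globals)) {
    if (identical(model$globals[[gn]]$generated_by, name)) {
      model$globals[[gn]] <- NULL
    }
  }
  model
}
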