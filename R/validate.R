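# Consistency checking. Every check yields diagnostics, never aborts;
# validate() is pure (two calls on the same model give identical lists).
#
# Severity policy: an undefined reference in an expression is an error;
# an auto-created species is a warning (raised at build time); an empty
# expansion range is a warning; structural impossibilities (operator out
# of range, incompatible transfer, role mismatch) are errors.

#' Validate a model
#'
#' Runs all consistency checks: range coherence of succ/pred operators
#' (the successor of the last state of a non-circular list is not
#' defined), transfer-of-state compatibility, static computability of
#' range bounds, undefined identifiers in expressions, function-call
#' arity and parameter-role agreement, and SUM restrictions against the
#' species' state lists.
#'
#' @param model an `msl_model` from [build_model()].
#' @return list of [msl_issue()] objects (empty when the model is clean).
#' @export
validate <- function(model) {
  ic <- issue_collector()
  lists <- resolve_all_statelists(model, ic)
  check_globals(model, ic, lists)
  check_functions(model, ic)
  check_species(model, ic, lists)
  for (r in model$reactions) check_reaction(model, r, ic, lists)
  check_complex_restrictions(model, ic, lists)
  ic$issues
}

# Resolve every site's state list once; NULL where resolution failed.
# Key: "<species>\r<site>" (\r cannot occur in identifiers).
sl_key <- function(sp, site) paste(sp, site, sep = "\r")

resolve_all_statelists <- function(model, ic) {
  lists <- list()
  for (sp in model$species) {
    for (site in sp$sites) {
      key <- sl_key(sp$name, site$name)
      res <- tryCatch(resolve_state_list(site, model$globals),
                      msl_static_error = function(e) e)
      if (inherits(res, "msl_static_error")) {
        ic$add_at("error", "range_not_static",
                  sprintf("state range of site '%s' of species '%s' is not statically computable: %s",
                          site$name, sp$name, conditionMessage(res)),
                  node_pos(site))
        lists[key] <- list(NULL)
      } else {
        if (!is.null(attr(res, "empty_range"))) {
          ic$add_at("warning", "empty_range",
                    sprintf("site '%s' of species '%s': %s", site$name,
                            sp$name, attr(res, "empty_range")),
                    node_pos(site))
        }
        lists[[key]] <- res
      }
    }
  }
  lists
}

get_site <- function(model, sp_name, site_name) {
  sp <- model$species[[sp_name]]
  if (is.null(sp)) return(NULL)
  for (s in sp$sites) if (identical(s$name, site_name)) return(s)
  NULL
}

site_names_of <- function(sp) vapply(sp$sites, `[[`, "", "name")

# ------------------------------------------------------ expression checks

# ctx: human-readable owner ("expression of global 'k1'"); allowed: when
# non-NULL, the only legal bare identifiers (function bodies).
check_expr <- function(model, expr, ctx, ic, lists, allowed = NULL,
                       self_species = NULL) {
  if (is.null(expr)) return(invisible(NULL))
  expr_walk(expr, function(n) {
    if (identical(n$kind, "ident")) {
      known <- if (is.null(allowed)) {
        !is.null(model$globals[[n$name]]) || !is.null(model$species[[n$name]])
      } else {
        n$name %in% allowed
      }
      if (!known) {
        ic$add_at("error", "undefined_ref",
                  sprintf("%s references '%s', which is not defined", ctx, n$name),
                  node_pos(n))
      }
    } else if (identical(n$kind, "accessor")) {
      if (is.null(model$species[[n$species]])) {
        ic$add_at("error", "undefined_ref",
                  sprintf("%s references '%s.%s' but species '%s' is not defined",
                          ctx, n$species, n$site, n$species), node_pos(n))
      } else if (is.null(get_site(model, n$species, n$site))) {
        ic$add_at("error", "undefined_site",
                  sprintf("%s references '%s.%s' but '%s' has no site '%s'",
                          ctx, n$species, n$site, n$species, n$site), node_pos(n))
      }
    } else if (identical(n$kind, "call")) {
      f <- model$functions[[n$fn]]
      if (is.null(f)) {
        ic$add_at("error", "undefined_function",
                  sprintf("%s calls undefined function '%s'", ctx, n$fn),
                  node_pos(n))
      } else if (length(n$args) != length(f$params)) {
        ic$add_at("error", "bad_arity",
                  sprintf("%s calls '%s' with %d argument(s); %d expected",
                          ctx, n$fn, length(n$args), length(f$params)),
                  node_pos(n))
      }
    } else if (identical(n$kind, "sum")) {
      check_sum(model, n, ctx, ic, lists)
    }
  })
  invisible(NULL)
}

check_sum <- function(model, n, ctx, ic, lists) {
  sp <- model$species[[n$species]]
  if (is.null(sp)) {
    ic$add_at("error", "undefined_species",
              sprintf("%s: SUM over undefined species '%s'", ctx, n$species),
              node_pos(n))
    return(invisible(NULL))
  }
  for (r in n$restr) {
    site <- get_site(model, n$species, r$site)
    if (is.null(site)) {
      ic$add_at("error", "undefined_site",
                sprintf("%s: SUM restricts site '%s' but species '%s' has no such site",
                        ctx, r$site, n$species), node_pos(n))
      next
    }
    states <- lists[[sl_key(n$species, r$site)]]
    if (is.null(states)) next
    if (identical(r$kind, "enumset")) {
      bad <- setdiff(r$labels, states$labels)
      if (length(bad)) {
        ic$add_at("error", "sum_out_of_range",
                  sprintf("%s: SUM restriction state '%s' is not a state of %s.%s",
                          ctx, bad[[1]], n$species, r$site), node_pos(n))
      }
    } else if (identical(r$kind, "range")) {
      lo <- tryCatch(evaluate_static(r$lo, model$globals),
                     msl_static_error = function(e) NULL)
      hi <- tryCatch(evaluate_static(r$hi, model$globals),
                     msl_static_error = function(e) NULL)
      # bounds with per-instance accessors (e.g. a moving window) are
      # resolved at expansion time; only static bounds are checked here
      if (!is.null(lo) && !is.null(hi)) {
        if (!states$numeric) {
          ic$add_at("error", "sum_out_of_range",
                    sprintf("%s: numeric SUM range on non-numeric states of %s.%s",
                            ctx, n$species, r$site), node_pos(n))
        } else if (!any(states$values >= lo & states$values <= hi)) {
          ic$add_at("error", "sum_out_of_range",
                    sprintf("%s: SUM restriction {%s:%s} selects no state of %s.%s",
                            ctx, format_num(lo), format_num(hi), n$species,
                            r$site), node_pos(n))
        }
      }
    }
  }
  if (!is.null(n$weight)) check_expr(model, n$weight, ctx, ic, lists)
  invisible(NULL)
}

# ------------------------------------------------------------ block checks

check_globals <- function(model, ic, lists) {
  for (g in model$globals) {
    check_expr(model, g$expr, sprintf("expression of global quantity '%s'", g$name),
               ic, lists)
    if (identical(g$role, "fixed")) {
      err <- tryCatch({ static_eval(g$expr, model$globals, character()); NULL },
                      msl_static_error = function(e) e)
      if (!is.null(err) && grepl("circular", conditionMessage(err))) {
        ic$add_at("error", "circular_definition",
                  sprintf("global quantity '%s': %s", g$name, conditionMessage(err)),
                  node_pos(g))
      }
    }
  }
}

check_functions <- function(model, ic) {
  for (f in model$functions) {
    params <- vapply(f$params, `[[`, "", "name")
    if (anyDuplicated(params)) {
      ic$add_at("error", "duplicate_name",
                sprintf("function '%s' has duplicate parameter names", f$name),
                node_pos(f))
    }
    expr_walk(f$body, function(n) {
      if (identical(n$kind, "ident") && !n$name %in% params) {
        ic$add_at("error", "undefined_ref",
                  sprintf("body of function '%s' references '%s', which is not a parameter",
                          f$name, n$name), node_pos(n))
      } else if (n$kind %in% c("accessor", "sum")) {
        ic$add_at("error", "bad_ref",
                  sprintf("body of function '%s' may only reference its parameters",
                          f$name), node_pos(n))
      }
    })
  }
}

check_species <- function(model, ic, lists) {
  for (sp in model$species) {
    snames <- site_names_of(sp)
    empty_sites <- vapply(sp$sites, function(s) identical(s$kind, "empty"), TRUE)
    if (any(empty_sites) && is.null(sp$assignment)) {
      ic$add_at("error", "assignment_required",
                sprintf("species '%s' has site(s) without state values and must be defined by an assignment",
                        sp$name), sp$pos %||% c(NA, NA))
    }
    if (!is.null(sp$default_initial)) {
      check_expr(model, sp$default_initial,
                 sprintf("initial value of species '%s'", sp$name), ic, lists)
    }
    if (!is.null(sp$assignment)) {
      check_expr(model, sp$assignment,
                 sprintf("assignment of species '%s'", sp$name), ic, lists,
                 self_species = sp$name)
    }
    for (key in names(sp$per_state)) {
      pairs <- strsplit(strsplit(key, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      for (p in pairs) {
        states <- lists[[sl_key(sp$name, p[[1]])]]
        if (!p[[1]] %in% snames) {
          ic$add("error", "bad_initial",
                 sprintf("per-state initial of '%s' names unknown site '%s'",
                         sp$name, p[[1]]))
        } else if (!is.null(states) && !p[[2]] %in% states$labels) {
          ic$add("error", "bad_initial",
                 sprintf("per-state initial of '%s': '%s' is not a state of site '%s'",
                         sp$name, p[[2]], p[[1]]))
        }
      }
      check_expr(model, sp$per_state[[key]],
                 sprintf("per-state initial of species '%s'", sp$name), ic, lists)
    }
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ------------------------------------------------------------- reactions

check_reaction <- function(model, rxn, ic, lists) {
  ctx <- sprintf("reaction '%s'", rxn$name)
  pos <- node_pos(rxn)

  ref_species_ok <- function(ref) {
    if (is.null(model$species[[ref$species]])) {
      ic$add_at("error", "undefined_species",
                sprintf("%s references undefined species '%s'", ctx, ref$species),
                node_pos(ref))
      return(FALSE)
    }
    sp <- model$species[[ref$species]]
    ok <- TRUE
    for (site in names(ref$patterns)) {
      key_site <- if (identical(ref$patterns[[site]]$kind, "opcall")) {
        ref$patterns[[site]]$site
      } else site
      if (!key_site %in% site_names_of(sp)) {
        ic$add_at("error", "undefined_site",
                  sprintf("%s: species '%s' has no site '%s'", ctx,
                          ref$species, key_site), node_pos(ref))
        ok <- FALSE
      }
    }
    ok
  }

  # admitted states of a reactant occurrence's site (NULL if unresolvable)
  reactant_admitted <- function(ref, site) {
    states <- lists[[sl_key(ref$species, site)]]
    if (is.null(states)) return(NULL)
    pat <- ref$patterns[[site]]
    if (!is.null(pat) && pat$kind %in% c("opcall", "transfer")) return(NULL)
    tryCatch(pattern_admitted(pat, states, model$globals),
             error = function(e) { NULL })
  }

  reactant_names <- vapply(rxn$reactants, `[[`, "", "species")

  # reactants: no operator calls or transfers; patterns resolvable
  for (ref in rxn$reactants) {
    if (!ref_species_ok(ref)) next
    for (site in names(ref$patterns)) {
      pat <- ref$patterns[[site]]
      if (pat$kind %in% c("opcall", "transfer")) {
        ic$add_at("error", "bad_pattern",
                  sprintf("%s: %s is only legal in products or modifier assignments",
                          ctx, if (pat$kind == "opcall") sprintf("operator '%s'", pat$op)
                               else "transfer of state"),
                  node_pos(pat))
        next
      }
      states <- lists[[sl_key(ref$species, site)]]
      if (is.null(states)) next
      res <- tryCatch(pattern_admitted(pat, states, model$globals),
                      error = function(e) e)
      if (inherits(res, "error")) {
        ic$add_at("error", "bad_pattern",
                  sprintf("%s: reactant '%s', site '%s': %s", ctx, ref$species,
                          site, conditionMessage(res)), node_pos(pat))
      } else if (length(res) == 0) {
        ic$add_at("warning", "empty_range",
                  sprintf("%s: reactant '%s' admits no state for site '%s' (empty expansion)",
                          ctx, ref$species, site), node_pos(pat))
      }
    }
  }

  # source reactant occurrence for an operator/transfer target
  find_source <- function(species) {
    hits <- which(reactant_names == species)
    if (length(hits) == 0) return(NULL)
    if (length(hits) > 1) {
      ic$add_at("error", "ambiguous_source",
                sprintf("%s: species '%s' occurs %d times as a reactant; operator/transfer source is ambiguous",
                        ctx, species, length(hits)), pos)
    }
    rxn$reactants[[hits[[1]]]]
  }

  check_op_boundary <- function(op, src_ref, src_site, where) {
    states <- lists[[sl_key(src_ref$species, src_site)]]
    if (is.null(states) || states$circular) return(invisible(NULL))
    admitted <- reactant_admitted(src_ref, src_site)
    if (is.null(admitted) || length(admitted) == 0) return(invisible(NULL))
    n <- length(states$labels)
    if (op == "succ" && states$labels[[n]] %in% admitted) {
      ic$add_at("error", "succ_out_of_range",
                sprintf("%s: the successor of state %s is not defined for species '%s' (site '%s' ranges over {%s})",
                        ctx, states$labels[[n]], src_ref$species, src_site,
                        paste(states$labels, collapse = ",")), pos)
    } else if (op == "pred" && states$labels[[1]] %in% admitted) {
      ic$add_at("error", "pred_out_of_range",
                sprintf("%s: the predecessor of state %s is not defined for species '%s' (site '%s' ranges over {%s})",
                        ctx, states$labels[[1]], src_ref$species, src_site,
                        paste(states$labels, collapse = ",")), pos)
    }
    invisible(NULL)
  }

  check_output_ref <- function(ref, role) {
    if (!ref_species_ok(ref)) return(invisible(NULL))
    sp <- model$species[[ref$species]]
    carried <- ref$species %in% reactant_names
    for (site_name in site_names_of(sp)) {
      pat <- ref$patterns[[site_name]]
      target_states <- lists[[sl_key(ref$species, site_name)]]
      if (is.null(pat) || identical(pat$kind, "any")) {
        site_def <- get_site(model, ref$species, site_name)
        if (!is.null(site_def) && identical(site_def$kind, "empty")) next
        next_ok <- carried || is.null(target_states) ||
          length(target_states$labels) <= 1
        if (!next_ok) {
          ic$add_at("error", "unresolved_site",
                    sprintf("%s: %s '%s' leaves multistate site '%s' unresolved (fix a state, use an operator, or transfer it)",
                            ctx, role, ref$species, site_name), node_pos(ref))
        }
        next
      }
      if (pat$kind %in% c("range", "enumset")) {
        ic$add_at("error", "bad_pattern",
                  sprintf("%s: %s '%s' cannot use a state range on site '%s'",
                          ctx, role, ref$species, site_name), node_pos(pat))
      } else if (pat$kind == "fixed") {
        if (!is.null(target_states) && !pat$label %in% target_states$labels) {
          ic$add_at("error", "bad_pattern",
                    sprintf("%s: state '%s' is not a state of %s.%s", ctx,
                            pat$label, ref$species, site_name), node_pos(pat))
        }
      } else if (pat$kind == "opcall") {
        src <- find_source(ref$species)
        if (is.null(src)) {
          ic$add_at("error", "op_source_missing",
                    sprintf("%s: '%s(%s)' in a %s requires '%s' among the reactants",
                            ctx, pat$op, pat$site, role, ref$species),
                    node_pos(pat))
        } else {
          check_op_boundary(pat$op, src, pat$site, role)
        }
      } else if (pat$kind == "transfer") {
        src <- find_source(pat$src_species)
        if (is.null(src)) {
          ic$add_at("error", "transfer_source_missing",
                    sprintf("%s: transfer source '%s.%s' is not among the reactants",
                            ctx, pat$src_species, pat$src_site), node_pos(pat))
          next
        }
        if (is.null(get_site(model, pat$src_species, pat$src_site))) {
          ic$add_at("error", "undefined_site",
                    sprintf("%s: transfer source '%s' has no site '%s'", ctx,
                            pat$src_species, pat$src_site), node_pos(pat))
          next
        }
        if (!is.null(pat$op)) check_op_boundary(pat$op, src, pat$src_site, role)
        src_states <- lists[[sl_key(pat$src_species, pat$src_site)]]
        admitted <- reactant_admitted(src, pat$src_site)
        # a stateless target site (assignment species) accepts any value
        if (!is.null(admitted) && !is.null(src_states) &&
            !is.null(target_states) && length(target_states$labels) > 0) {
          mapped <- tryCatch(
            vapply(admitted, function(s) apply_state_op(src_states, s, pat$op),
                   character(1)),
            error = function(e) NULL)
          if (!is.null(mapped)) {
            bad <- setdiff(mapped, target_states$labels)
            if (length(bad)) {
              ic$add_at("error", "transfer_incompatible",
                        sprintf("%s: transferred state '%s' from %s.%s is not a legal state of %s.%s",
                                ctx, bad[[1]], pat$src_species, pat$src_site,
                                ref$species, site_name), node_pos(pat))
            }
          }
        }
      }
    }
    invisible(NULL)
  }

  for (ref in rxn$products) check_output_ref(ref, "product")
  for (ref in rxn$modifiers) check_output_ref(ref, "modifier")

  check_rate(model, rxn, ic, lists, ctx)
  invisible(NULL)
}

check_rate <- function(model, rxn, ic, lists, ctx) {
  participants <- vapply(c(rxn$reactants, rxn$modifiers), `[[`, "", "species")
  rate <- rxn$rate
  if (is.null(rate)) {
    ic$add_at("warning", "no_rate",
              sprintf("%s has no rate law; mass action with rate 1 is assumed at expansion",
                      ctx), node_pos(rxn))
    return(invisible(NULL))
  }
  if (identical(rate$kind, "rate_ma")) {
    check_expr(model, rate$rate, sprintf("%s (mass-action rate)", ctx), ic, lists)
    return(invisible(NULL))
  }
  if (identical(rate$kind, "rate_k")) {
    return(invisible(NULL))  # explicit formula over flat names; not resolvable here
  }
  call <- rate$call
  f <- model$functions[[call$fn]]
  if (is.null(f)) {
    ic$add_at("error", "undefined_function",
              sprintf("%s: rate law calls undefined function '%s'", ctx, call$fn),
              node_pos(call))
    return(invisible(NULL))
  }
  if (length(call$args) != length(f$params)) {
    ic$add_at("error", "bad_arity",
              sprintf("%s: '%s' expects %d argument(s), got %d", ctx, call$fn,
                      length(f$params), length(call$args)), node_pos(call))
    return(invisible(NULL))
  }
  for (i in seq_along(f$params)) {
    p <- f$params[[i]]
    a <- call$args[[i]]
    if (p$role == "GLQ") {
      ok <- identical(a$kind, "num") ||
        (identical(a$kind, "ident") && !is.null(model$globals[[a$name]]))
      if (!ok) {
        ic$add_at("error", "bad_role",
                  sprintf("%s: argument %d of '%s' (role GLQ) must be a number or a global quantity",
                          ctx, i, call$fn), node_pos(a))
      }
    } else if (p$role == "SITE") {
      if (!identical(a$kind, "accessor")) {
        ic$add_at("error", "bad_role",
                  sprintf("%s: argument %d of '%s' (role SITE) must be a species.site accessor",
                          ctx, i, call$fn), node_pos(a))
      } else if (!a$species %in% participants) {
        ic$add_at("error", "bad_role",
                  sprintf("%s: SITE argument '%s.%s' must reference a reactant or modifier of the reaction",
                          ctx, a$species, a$site), node_pos(a))
      } else {
        states <- lists[[sl_key(a$species, a$site)]]
        if (is.null(get_site(model, a$species, a$site))) {
          ic$add_at("error", "undefined_site",
                    sprintf("%s: SITE argument references '%s.%s' but there is no such site",
                            ctx, a$species, a$site), node_pos(a))
        } else if (!is.null(states) && length(states$labels) > 0 && !states$numeric) {
          ic$add_at("error", "site_not_numeric",
                    sprintf("%s: SITE argument '%s.%s' has non-integer state labels; a numeric binding is impossible",
                            ctx, a$species, a$site), node_pos(a))
        }
      }
    } else if (p$role == "SUB") {
      ok <- identical(a$kind, "ident") && a$name %in% participants
      if (!ok) {
        ic$add_at("error", "bad_role",
                  sprintf("%s: argument %d of '%s' (role SUB) must name a reactant or modifier species",
                          ctx, i, call$fn), node_pos(a))
      }
    }
  }
  invisible(NULL)
}

check_complex_restrictions <- function(model, ic, lists) {
  for (sp in model$species) {
    if (is.null(sp$complex_of)) next
    for (site in sp$sites) {
      if (is.null(site$tracks)) next
      comp_states <- lists[[sl_key(site$tracks[[1]], site$tracks[[2]])]]
      own_states <- lists[[sl_key(sp$name, site$name)]]
      if (is.null(comp_states) || is.null(own_states)) next
      bad <- setdiff(own_states$labels, comp_states$labels)
      if (length(bad)) {
        ic$add("error", "restriction_invalid",
               sprintf("complex '%s': restricted state '%s' of site '%s' is not a state of component %s.%s",
                       sp$name, bad[[1]], site$name, site$tracks[[1]],
                       site$tracks[[2]]))
      }
    }
  }
}
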