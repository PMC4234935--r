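# Semantic model (intermediate representation) built from the AST.
#
# An msl_model holds named lists of species, reactions, global
# quantities, rate functions and complex declarations, plus the verbatim
# entries that failed to parse. Everything stays representable even when
# inconsistent; validate() reports problems without mutating anything.

default_config <- function() {
  list(autocompletion = "silent",  # off | confirm | silent
       default_initial = 0,        # initial amount for auto-created species
       default_delete = "cascade") # cascade | replace | leave
}

#' Build a semantic model from a parsed AST
#'
#' Performs name collection, materializes complex declarations into
#' species (and, when requested, complexation/decomplexation reactions
#' with transfer of state), attaches per-state initial overrides, and
#' applies the autocompletion policy to species that are referenced in
#' reactions but never defined:
#'
#' * `"silent"` -- the species is created with the configured default
#'   initial amount and a warning issue is recorded;
#' * `"off"` -- nothing is created and an error issue (a major
#'   inconsistency) is recorded;
#' * `"confirm"` -- the names are returned in `pending` for the caller
#'   to resolve.
#'
#' Nothing is fatal: the model is returned in all cases together with
#' the list of issues raised so far (parse diagnostics carried by the
#' AST are included).
#'
#' @param ast a `model_ast` from [parse_model()].
#' @param policy autocompletion policy; overrides `config$autocompletion`.
#' @param config named list; see [default_config()] / [read_config()].
#' @return list with elements `model` (an `msl_model`), `issues` and
#'   `pending` (character vector of unresolved names under `"confirm"`).
#' @export
build_model <- function(ast, policy = NULL, config = list()) {
  cfg <- utils::modifyList(default_config(), config)
  if (!is.null(policy)) cfg$autocompletion <- policy
  stopifnot(cfg$autocompletion %in% c("off", "confirm", "silent"))
  ic <- issue_collector()
  for (d in ast$diagnostics) ic$issues[[length(ic$issues) + 1L]] <- d

  model <- structure(list(species = list(), reactions = list(),
                          globals = list(), functions = list(),
                          complexes = list(), raw = ast$raw, config = cfg),
                     class = "msl_model")

  for (g in ast$globals) {
    if (!is.null(model$globals[[g$name]])) {
      ic$add_at("error", "duplicate_name",
                sprintf("global quantity '%s' defined more than once", g$name),
                node_pos(g))
      next
    }
    model$globals[[g$name]] <- g
  }
  for (f in ast$functions) {
    if (!is.null(model$functions[[f$name]])) {
      ic$add_at("error", "duplicate_name",
                sprintf("function '%s' defined more than once", f$name),
                node_pos(f))
      next
    }
    model$functions[[f$name]] <- f
  }
  for (se in ast$species) {
    nm <- se$def$name
    if (!is.null(model$species[[nm]])) {
      ic$add_at("error", "duplicate_name",
                sprintf("species '%s' defined more than once", nm),
                node_pos(se))
      next
    }
    model$species[[nm]] <- list(name = nm, sites = se$def$sites,
                                default_initial = se$initial,
                                assignment = se$assignment,
                                per_state = list(), generated_by = NULL,
                                pos = node_pos(se))
  }

  # per-state initial overrides; unlisted states inherit the default
  for (iv in ast$initials) {
    sp <- model$species[[iv$ref$species]]
    if (is.null(sp)) {
      ic$add_at("error", "undefined_species",
                sprintf("initial value for undefined species '%s'", iv$ref$species),
                node_pos(iv))
      next
    }
    key <- per_state_key(iv$ref, sp)
    if (is.null(key)) {
      ic$add_at("error", "bad_initial",
                sprintf("initial override for '%s' must fix every site to one state",
                        iv$ref$species), node_pos(iv))
      next
    }
    model$species[[iv$ref$species]]$per_state[[key]] <- iv$value
  }

  rn <- 0L
  for (r in ast$reactions) {
    if (is.null(r$name)) {
      repeat {
        rn <- rn + 1L
        cand <- paste0("r", rn)
        if (is.null(model$reactions[[cand]])) break
      }
      r$name <- cand
    }
    if (!is.null(model$reactions[[r$name]])) {
      ic$add_at("error", "duplicate_name",
                sprintf("reaction '%s' defined more than once", r$name),
                node_pos(r))
      next
    }
    r$generated_by <- NULL
    model$reactions[[r$name]] <- r
  }

  for (cx in ast$complexes) {
    model <- materialize_complex(model, cx, ic)
  }

  # autocompletion of species referenced but never defined
  missing <- setdiff(referenced_species(model), names(model$species))
  pending <- character()
  if (length(missing)) {
    if (cfg$autocompletion == "silent") {
      for (nm in missing) {
        model$species[[nm]] <- list(
          name = nm, sites = infer_sites(model, nm),
          default_initial = e_num(cfg$default_initial),
          assignment = NULL, per_state = list(), generated_by = NULL,
          pos = c(NA_integer_, NA_integer_))
        ic$add("warning", "autocreated_species",
               sprintf("species '%s' was referenced but not defined; created with default initial %s",
                       nm, format_num(cfg$default_initial)))
      }
    } else if (cfg$autocompletion == "off") {
      for (nm in missing) {
        ic$add("error", "undefined_species",
               sprintf("major issue: species '%s' is used in a reaction but never defined", nm))
      }
    } else {
      pending <- missing
      for (nm in missing) {
        ic$add("info", "pending_species",
               sprintf("species '%s' is referenced but not defined; awaiting confirmation", nm))
      }
    }
  }

  list(model = model, issues = ic$issues, pending = pending)
}

# canonical per-state key "p=0" / "a=0,b=free" in site declaration order;
# NULL if the ref does not fix every site exactly once
per_state_key <- function(ref, sp) {
  site_names <- vapply(sp$sites, `[[`, "", "name")
  if (!setequal(names(ref$patterns), site_names)) return(NULL)
  labels <- character(length(site_names))
  for (i in seq_along(site_names)) {
    pat <- ref$patterns[[site_names[[i]]]]
    if (is.null(pat) || !identical(pat$kind, "fixed")) return(NULL)
    labels[[i]] <- pat$label
  }
  paste(paste0(site_names, "=", labels), collapse = ",")
}

state_key <- function(site_names, labels) {
  if (length(site_names) == 0) return("")
  paste(paste0(site_names, "=", labels), collapse = ",")
}

# every species name referenced by reactions, complexes, SUMs, accessors
referenced_species <- function(model) {
  out <- character()
  grab_expr <- function(expr) {
    if (is.null(expr)) return()
    expr_walk(expr, function(n) {
      if (identical(n$kind, "sum")) out[[length(out) + 1L]] <<- n$species
    })
  }
  for (r in model$reactions) {
    for (ref in c(r$reactants, r$products, r$modifiers)) {
      out[[length(out) + 1L]] <- ref$species
    }
    if (!is.null(r$rate)) {
      grab_expr(if (identical(r$rate$kind, "rate_ma")) r$rate$rate else r$rate$call)
    }
  }
  for (sp in model$species) grab_expr(sp$assignment)
  for (g in model$globals) grab_expr(g$expr)
  for (cx in model$complexes) {
    for (comp in cx$components) out[[length(out) + 1L]] <- comp$species
  }
  unique(out)
}

# Site structure for an auto-created species, inferred from the explicit
# state patterns used in its references (ranges and enumerations only;
# operator or transfer patterns carry no state-list information).
infer_sites <- function(model, species_name) {
  sites <- list()
  for (r in model$reactions) {
    for (ref in c(r$reactants, r$products, r$modifiers)) {
      if (!identical(ref$species, species_name)) next
      for (site in names(ref$patterns)) {
        if (!is.null(sites[[site]])) next
        pat <- ref$patterns[[site]]
        if (pat$kind == "range") {
          sites[[site]] <- list(name = site, kind = "range", lo = pat$lo,
                                hi = pat$hi, circular = FALSE)
        } else if (pat$kind %in% c("enumset", "fixed")) {
          labels <- if (pat$kind == "fixed") pat$label else pat$labels
          sites[[site]] <- list(name = site, kind = "enumset",
                                labels = labels, circular = FALSE)
        }
      }
    }
  }
  unname(sites)
}

# ---------------------------------------------------------------- complexes

# Turn a complex declaration into a species (tracked sites copied from
# the components, state lists restricted as declared) and optionally into
# the complexation/decomplexation reaction pair with transfer of state.
materialize_complex <- function(model, cx, ic) {
  comp_names <- vapply(cx$components, `[[`, "", "species")
  auto <- is.null(cx$name)
  name <- if (auto) paste(comp_names, collapse = "_") else cx$name
  cx$name <- name
  cx$auto_name <- auto
  if (!is.null(model$complexes[[name]]) || !is.null(model$species[[name]])) {
    ic$add_at("error", "duplicate_name",
              sprintf("complex name '%s' is already in use", name), node_pos(cx))
    return(model)
  }
  sites <- list()
  ok <- TRUE
  for (comp in cx$components) {
    sp <- model$species[[comp$species]]
    if (is.null(sp)) {
      ic$add_at("error", "undefined_species",
                sprintf("complex '%s' uses undefined component '%s'",
                        name, comp$species), node_pos(cx))
      ok <- FALSE
      next
    }
    if (!is.null(sp$complex_of)) {
      ic$add_at("error", "nested_complex",
                sprintf("complex '%s': component '%s' is itself a complex (nesting is not supported)",
                        name, comp$species), node_pos(cx))
      ok <- FALSE
      next
    }
    comp_site_names <- vapply(sp$sites, `[[`, "", "name")
    for (site in names(comp$patterns)) {
      pat <- comp$patterns[[site]]
      idx <- match(site, comp_site_names)
      if (is.na(idx)) {
        ic$add_at("error", "undefined_site",
                  sprintf("complex '%s': component '%s' has no site '%s'",
                          name, comp$species, site), node_pos(cx))
        ok <- FALSE
        next
      }
      taken <- vapply(sites, `[[`, "", "name")
      new_name <- if (site %in% taken) paste(comp$species, site, sep = "_") else site
      src_def <- sp$sites[[idx]]
      site_def <- switch(pat$kind,
        any = { d <- src_def; d$name <- new_name; d },
        range = list(name = new_name, kind = "range", lo = pat$lo, hi = pat$hi,
                     circular = FALSE),
        enumset = list(name = new_name, kind = "enumset", labels = pat$labels,
                       circular = FALSE),
        fixed = list(name = new_name, kind = "enumset", labels = pat$label,
                     circular = FALSE),
        { ic$add_at("error", "bad_pattern",
                    sprintf("complex '%s': illegal tracking pattern on site '%s'",
                            name, site), node_pos(cx))
          ok <- FALSE
          NULL })
      if (!is.null(site_def)) {
        site_def$tracks <- c(comp$species, site)
        sites[[length(sites) + 1L]] <- site_def
      }
    }
  }
  model$complexes[[name]] <- cx
  if (!ok) return(model)
  model$species[[name]] <- list(name = name, sites = sites,
                                default_initial = e_num(model$config$default_initial),
                                assignment = NULL, per_state = list(),
                                generated_by = name, complex_of = comp_names,
                                pos = node_pos(cx))
  if (isTRUE(cx$generate_reactions)) {
    for (g in c(paste0(name, "_kon"), paste0(name, "_koff"))) {
      if (is.null(model$globals[[g]])) {
        model$globals[[g]] <- node("global", name = g, role = "fixed",
                                   expr = e_num(1))
        model$globals[[g]]$generated_by <- name
      }
    }
    bind_reactants <- cx$components
    bind_product <- node("species_ref", species = name, patterns = local({
      pats <- list()
      for (s in sites) pats[[s$name]] <- node("transfer",
                                              src_species = s$tracks[[1]],
                                              src_site = s$tracks[[2]], op = NULL)
      pats
    }))
    unbind_products <- lapply(cx$components, function(comp) {
      pats <- list()
      for (s in sites) {
        if (identical(s$tracks[[1]], comp$species)) {
          pats[[s$tracks[[2]]]] <- node("transfer", src_species = name,
                                        src_site = s$name, op = NULL)
        }
      }
      node("species_ref", species = comp$species, patterns = pats)
    })
    model$reactions[[paste0(name, "_bind")]] <-
      node("reaction", name = paste0(name, "_bind"),
           reactants = bind_reactants, products = list(bind_product),
           modifiers = list(),
           rate = node("rate_ma", rate = e_ident(paste0(name, "_kon"))),
           generated_by = name)
    model$reactions[[paste0(name, "_unbind")]] <-
      node("reaction", name = paste0(name, "_unbind"),
           reactants = list(node("species_ref", species = name,
                                 patterns = list())),
           products = unbind_products, modifiers = list(),
           rate = node("rate_ma", rate = e_ident(paste0(name, "_koff"))),
           generated_by = name)
  }
  model
}

#' Build a complex species programmatically
#'
#' Equivalent to a `[complexes]` declaration: adds a species whose sites
#' are the tracked component sites (optionally restricted to a state
#' subrange) and, when `generate_reactions` is `TRUE`, the
#' complexation/decomplexation reaction pair using transfer of state with
#' auto-created rate constants `<name>_kon` / `<name>_koff`.
#'
#' @param model an `msl_model`.
#' @param components character vector of component declarations in
#'   reference syntax, e.g. `c("Net1(p{0:5})", "Cdc14")`: a bare site
#'   name tracks the full state list, a braced range restricts it.
#' @param name complex name; when `NULL` an auto-maintained name is
#'   derived from the component names.
#' @param generate_reactions add the reaction pair.
#' @return list with elements `model`, `complex` (the declaration as
#'   stored) and `issues`.
#' @export
build_complex <- function(model, components, name = NULL,
                          generate_reactions = FALSE) {
  refs <- lapply(components, function(txt) {
    ts <- token_stream(msl_tokenize(txt))
    parse_species_ref_ts(ts)
  })
  cx <- node("complex_decl", name = name, components = refs,
             generate_reactions = generate_reactions)
  ic <- issue_collector()
  model <- materialize_complex(model, cx, ic)
  nm <- if (is.null(name)) paste(vapply(refs, `[[`, "", "species"), collapse = "_") else name
  list(model = model, complex = model$complexes[[nm]], issues = ic$issues)
}

# ------------------------------------------------------- static evaluation

#' Statically evaluate an expression over fixed global quantities
#'
#' Range bounds and other structural values must be computable before
#' expansion: only numbers and fixed global quantities (recursively) are
#' allowed. A non-integer result is rounded down.
#'
#' @param expr an expression AST (or a string, parsed on the fly).
#' @param globals an `msl_model`, a named list of global nodes, or a
#'   named numeric vector.
#' @return an integer-valued number.
#' @examples
#' evaluate_static("high-1", c(high = 10))
#' evaluate_static("7.8", c())
#' @export
evaluate_static <- function(expr, globals = list()) {
  if (is.character(expr)) expr <- parse_expression(expr)
  genv <- normalize_globals(globals)
  floor(static_eval(expr, genv, character()))
}

normalize_globals <- function(globals) {
  if (inherits(globals, "msl_model")) return(globals$globals)
  if (is.numeric(globals)) {
    out <- lapply(seq_along(globals), function(i) {
      node("global", name = names(globals)[[i]], role = "fixed",
           expr = e_num(globals[[i]]))
    })
    names(out) <- names(globals)
    return(out)
  }
  globals
}

msl_static_error <- function(message) {
  stop(structure(class = c("msl_static_error", "error", "condition"),
                 list(message = message, call = NULL)))
}

static_eval <- function(expr, globals, visiting) {
  switch(expr$kind,
    num = expr$value,
    ident = {
      g <- globals[[expr$name]]
      if (is.null(g)) {
        msl_static_error(sprintf("'%s' is not a defined global quantity", expr$name))
      }
      if (!identical(g$role, "fixed")) {
        msl_static_error(sprintf("'%s' is an assigned quantity and not statically computable",
                                 expr$name))
      }
      if (expr$name %in% visiting) {
        msl_static_error(sprintf("circular definition of global quantity '%s'", expr$name))
      }
      static_eval(g$expr, globals, c(visiting, expr$name))
    },
    neg = -static_eval(expr$arg, globals, visiting),
    binop = {
      l <- static_eval(expr$lhs, globals, visiting)
      r <- static_eval(expr$rhs, globals, visiting)
      switch(expr$op, "+" = l + r, "-" = l - r, "*" = l * r,
             "/" = l / r, "^" = l^r)
    },
    accessor = msl_static_error(
      sprintf("site accessor '%s.%s' is not statically computable",
              expr$species, expr$site)),
    sum = msl_static_error("SUM aggregates are not statically computable"),
    call = msl_static_error(
      sprintf("function call '%s(...)' is not statically computable", expr$fn)),
    msl_static_error(sprintf("cannot evaluate node of kind '%s'", expr$kind)))
}

# ----------------------------------------------------------- serialization

# Convert a built model back to AST shape for unparse(); entities
# generated from complex declarations are omitted (regenerated on load).
model_to_ast <- function(model) {
  ast <- list(kind = "model_ast", species = list(), reactions = list(),
              globals = list(), functions = list(), complexes = list(),
              initials = list(), raw = model$raw, diagnostics = list())
  class(ast) <- "msl_ast"
  for (sp in model$species) {
    if (!is.null(sp$generated_by)) next
    sites <- lapply(sp$sites, function(s) { s$tracks <- NULL; s })
    ast$species[[length(ast$species) + 1L]] <-
      node("species_entry",
           def = node("species_def", name = sp$name, sites = sites),
           initial = sp$default_initial, assignment = sp$assignment)
    site_names <- vapply(sp$sites, `[[`, "", "name")
    for (key in names(sp$per_state)) {
      assign_pairs <- strsplit(strsplit(key, ",", fixed = TRUE)[[1]], "=", fixed = TRUE)
      pats <- list()
      for (p in assign_pairs) pats[[p[[1]]]] <- node("fixed", label = p[[2]])
      ast$initials[[length(ast$initials) + 1L]] <-
        node("initial_override",
             ref = node("species_ref", species = sp$name, patterns = pats),
             value = sp$per_state[[key]])
    }
  }
  for (g in model$globals) {
    if (!is.null(g$generated_by)) next
    ast$globals[[length(ast$globals) + 1L]] <- g
  }
  for (f in model$functions) ast$functions[[length(ast$functions) + 1L]] <- f
  for (r in model$reactions) {
    if (!is.null(r$generated_by)) next
    r$generated_by <- NULL
    ast$reactions[[length(ast$reactions) + 1L]] <- r
  }
  for (cx in model$complexes) {
    if (isTRUE(cx$auto_name)) cx$name <- NULL
    cx$auto_name <- NULL
    ast$complexes[[length(ast$complexes) + 1L]] <- cx
  }
  ast
}

#' Read and build a model from a .msl file
#'
#' @param path file path.
#' @param policy autocompletion policy (see [build_model()]).
#' @param config configuration overrides (see [read_config()]).
#' @return as [build_model()].
#' @export
read_msl <- function(path, policy = NULL, config = list()) {
  build_model(parse_model(readLines(path, warn = FALSE)), policy = policy,
              config = config)
}

#' Read a key=value configuration file
#'
#' Mirrors an editor preferences menu: recognized keys are
#' `autocompletion` (off/confirm/silent), `default_initial` (number) and
#' `default_delete` (cascade/replace/leave).
#'
#' @param path configuration file.
#' @return named list suitable for the `config` argument of
#'   [build_model()].
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  cfg <- list()
  for (ln in lines) {
    kv <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*?)\\s*$", ln))[[1]]
    if (length(kv) != 3L) stop("malformed config line: ", ln)
    val <- kv[[3]]
    if (grepl("^-?[0-9.]+$", val)) val <- as.numeric(val)
    cfg[[kv[[2]]]] <- val
  }
  allowed <- names(default_config())
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg
}

#' @export
print.msl_model <- function(x, ...) {
  n_gen_r <- sum(vapply(x$reactions, function(r) !is.null(r$generated_by), TRUE))
  cat(sprintf("<msl model> %d species, %d reactions%s, %d globals, %d functions, %d complexes\n",
              length(x$species), length(x$reactions),
              if (n_gen_r) sprintf(" (%d complex-generated)", n_gen_r) else "",
              length(x$globals), length(x$functions), length(x$complexes)))
  invisible(x)
}
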