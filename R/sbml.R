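# SBML Level 3 Version 1 (core) export of a flat model, plus a
# structural consistency checker for the written documents.
#
# Mapping: every flat species goes into one default compartment of size
# 1; mass-action and user-defined kinetics are written as explicit
# kinetic-law formulas; fixed globals become constant parameters;
# assignment rules cover SUM-derived quantities and per-instance
# modifiers (their species are flagged boundaryCondition so a rule may
# govern them). Identifiers are sanitized to the SBML SId grammar with
# the original name kept in the name attribute.

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
MATHML_NS <- "http://www.w3.org/1998/Math/MathML"

sanitize_sid <- function(x) {
  x <- gsub("[^A-Za-z0-9_]", "_", x)
  ifelse(grepl("^[0-9]", x), paste0("_", x), x)
}

# deterministic unique SIds; collisions get a numeric suffix
sid_map <- function(names) {
  ids <- sanitize_sid(names)
  seen <- list()
  collided <- character()
  for (i in seq_along(ids)) {
    id <- ids[[i]]
    if (!is.null(seen[[id]])) {
      k <- 2L
      while (!is.null(seen[[paste0(id, "_", k)]])) k <- k + 1L
      collided <- c(collided, names[[i]])
      id <- paste0(id, "_", k)
      ids[[i]] <- id
    }
    seen[[id]] <- TRUE
  }
  if (length(collided)) {
    warning("SBML id collision after sanitization; suffixed: ",
            paste(collided, collapse = ", "), call. = FALSE)
  }
  stats::setNames(ids, names)
}

#' Write a flat model as SBML Level 3 Version 1
#'
#' @param flat an `msl_flat_model` from [expand_model()].
#' @param path optional output file; the XML document is returned either
#'   way.
#' @param model_id id for the `<model>` element.
#' @return an `xml2::xml_document`.
#' @seealso [sbml_check()] for consistency checking of the output.
#' @export
write_sbml <- function(flat, path = NULL, model_id = "model") {
  entity_names <- c(vapply(flat$species, `[[`, "", "name"),
                    vapply(flat$parameters, `[[`, "", "name"),
                    vapply(flat$rules, function(r) r$variable, ""),
                    "default")
  ids <- sid_map(unique(entity_names))
  rule_vars <- vapply(flat$rules, `[[`, "", "variable")
  species_names <- vapply(flat$species, `[[`, "", "name")

  doc <- xml2::xml_new_root("sbml", xmlns = SBML_NS, level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = model_id)

  comps <- xml2::xml_add_child(mdl, "listOfCompartments")
  xml2::xml_add_child(comps, "compartment", id = ids[["default"]],
                      spatialDimensions = "3", size = "1", constant = "true")

  if (length(flat$species)) {
    lspecies <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (sp in flat$species) {
      attrs <- list(id = ids[[sp$name]], name = sp$name,
                    compartment = ids[["default"]],
                    hasOnlySubstanceUnits = "false",
                    boundaryCondition = if (sp$name %in% rule_vars) "true" else "false",
                    constant = "false")
      if (!is.na(sp$initial)) attrs$initialAmount <- format_num_sbml(sp$initial)
      do.call(xml2::xml_add_child, c(list(lspecies, "species"), attrs))
    }
  }

  assigned_globals <- setdiff(rule_vars, species_names)
  if (length(flat$parameters) || length(assigned_globals)) {
    lparams <- xml2::xml_add_child(mdl, "listOfParameters")
    for (p in flat$parameters) {
      attrs <- list(id = ids[[p$name]], name = p$name, constant = "true")
      if (!is.na(p$value)) attrs$value <- format_num_sbml(p$value)
      do.call(xml2::xml_add_child, c(list(lparams, "parameter"), attrs))
    }
    for (g in assigned_globals) {
      xml2::xml_add_child(lparams, "parameter", id = ids[[g]], name = g,
                          constant = "false")
    }
  }

  if (length(flat$rules)) {
    lrules <- xml2::xml_add_child(mdl, "listOfRules")
    for (r in flat$rules) {
      rule <- xml2::xml_add_child(lrules, "assignmentRule",
                                  variable = ids[[r$variable]])
      add_math(rule, r$expr, ids)
    }
  }

  if (length(flat$reactions)) {
    rids <- sid_map(paste0("rx_", vapply(flat$reactions, `[[`, "", "name")))
    lrx <- xml2::xml_add_child(mdl, "listOfReactions")
    for (i in seq_along(flat$reactions)) {
      r <- flat$reactions[[i]]
      rx <- xml2::xml_add_child(lrx, "reaction", id = rids[[i]], name = r$name,
                                reversible = "false", fast = "false")
      add_participants(rx, "listOfReactants", "speciesReference",
                       r$reactants, ids, with_stoich = TRUE)
      add_participants(rx, "listOfProducts", "speciesReference",
                       r$products, ids, with_stoich = TRUE)
      add_participants(rx, "listOfModifiers", "modifierSpeciesReference",
                       r$modifiers, ids, with_stoich = FALSE)
      kl <- xml2::xml_add_child(rx, "kineticLaw")
      add_math(kl, r$kinetic, ids)
    }
  }

  # re-parse so namespace declarations added as attributes become real
  # namespaces (xpath with a prefix then works on the returned document)
  doc <- xml2::read_xml(as.character(doc))
  if (!is.null(path)) xml2::write_xml(doc, path)
  doc
}

format_num_sbml <- function(x) format(x, scientific = FALSE, trim = TRUE)

add_participants <- function(rx, list_tag, ref_tag, names, ids, with_stoich) {
  if (length(names) == 0) return(invisible(NULL))
  lst <- xml2::xml_add_child(rx, list_tag)
  if (with_stoich) {
    # stoichiometry by repetition in the flat model; grouped here
    tab <- table(factor(names, levels = unique(names)))
    for (nm in names(tab)) {
      xml2::xml_add_child(lst, ref_tag, species = ids[[nm]],
                          stoichiometry = format_num_sbml(as.numeric(tab[[nm]])),
                          constant = "true")
    }
  } else {
    for (nm in unique(names)) {
      xml2::xml_add_child(lst, ref_tag, species = ids[[nm]])
    }
  }
  invisible(NULL)
}

# expression AST -> MathML under a new <math> child
add_math <- function(parent, expr, ids) {
  math <- xml2::xml_add_child(parent, "math", xmlns = MATHML_NS)
  add_math_node(math, expr, ids)
  math
}

add_math_node <- function(parent, e, ids) {
  switch(e$kind,
    num = {
      n <- xml2::xml_add_child(parent, "cn")
      if (e$value == round(e$value)) {
        xml2::xml_set_attr(n, "type", "integer")
        xml2::xml_set_text(n, format(as.integer(e$value)))
      } else {
        xml2::xml_set_text(n, format_num_sbml(e$value))
      }
    },
    ident = {
      id <- unname(ids[e$name])
      if (is.na(id)) id <- sanitize_sid(e$name)
      n <- xml2::xml_add_child(parent, "ci")
      xml2::xml_set_text(n, id)
    },
    neg = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, "minus")
      add_math_node(ap, e$arg, ids)
    },
    binop = {
      ap <- xml2::xml_add_child(parent, "apply")
      xml2::xml_add_child(ap, switch(e$op, "+" = "plus", "-" = "minus",
                                     "*" = "times", "/" = "divide",
                                     "^" = "power"))
      add_math_node(ap, e$lhs, ids)
      add_math_node(ap, e$rhs, ids)
    },
    call = {
      ap <- xml2::xml_add_child(parent, "apply")
      ci <- xml2::xml_add_child(ap, "ci")
      xml2::xml_set_text(ci, sanitize_sid(e$fn))
      for (a in e$args) add_math_node(ap, a, ids)
    },
    stop("cannot serialize expression node of kind '", e$kind,
         "' to MathML (not grounded?)"))
}

#' Structural consistency check of an SBML Level 3 Version 1 document
#'
#' Verifies the constraints that matter for a flat-model export: correct
#' namespace/level/version, globally unique SIds, presence of required
#' attributes, species referencing existing compartments, species
#' references and rule variables resolving to defined entities, at most
#' one rule per variable, no rule on a constant entity, rule-governed
#' species not consumed or produced by reactions, and every `<ci>`
#' symbol in kinetic laws and rules defined in the document.
#'
#' @param x an `xml2::xml_document` or a path to an SBML file.
#' @return character vector of error messages; `character(0)` means the
#'   document passes.
#' @export
sbml_check <- function(x) {
  doc <- if (inherits(x, "xml_document")) {
    xml2::read_xml(as.character(x))  # normalize in-memory namespaces
  } else {
    xml2::read_xml(x)
  }
  errs <- character()
  say <- function(...) errs <<- c(errs, sprintf(...))
  root <- xml2::xml_root(doc)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")

  if (!identical(xml2::xml_name(root), "sbml")) say("root element is not <sbml>")
  if (!identical(xml2::xml_attr(root, "level"), "3") ||
      !identical(xml2::xml_attr(root, "version"), "1")) {
    say("document is not Level 3 Version 1")
  }
  if (!SBML_NS %in% unlist(xml2::xml_ns(doc))) {
    say("missing SBML L3V1 core namespace")
  }

  attr_of <- function(nodes, a) xml2::xml_attr(nodes, a)
  compartments <- xml2::xml_find_all(doc, "//s:compartment", ns)
  species <- xml2::xml_find_all(doc, "//s:species", ns)
  params <- xml2::xml_find_all(doc, "//s:parameter", ns)
  reactions <- xml2::xml_find_all(doc, "//s:reaction", ns)
  rules <- xml2::xml_find_all(doc, "//s:assignmentRule", ns)

  all_ids <- c(attr_of(compartments, "id"), attr_of(species, "id"),
               attr_of(params, "id"), attr_of(reactions, "id"))
  if (anyNA(all_ids)) say("an entity is missing its required id attribute")
  dup <- all_ids[duplicated(all_ids)]
  for (d in unique(dup[!is.na(dup)])) say("duplicate SId '%s'", d)
  bad <- all_ids[!is.na(all_ids) & !grepl("^[A-Za-z_][A-Za-z0-9_]*$", all_ids)]
  for (b in unique(bad)) say("'%s' is not a valid SId", b)

  comp_ids <- attr_of(compartments, "id")
  sp_ids <- attr_of(species, "id")
  param_ids <- attr_of(params, "id")

  for (i in seq_along(species)) {
    s <- species[[i]]
    for (a in c("compartment", "hasOnlySubstanceUnits", "boundaryCondition",
                "constant")) {
      if (is.na(xml2::xml_attr(s, a))) {
        say("species '%s' lacks required attribute '%s'",
            xml2::xml_attr(s, "id"), a)
      }
    }
    cmp <- xml2::xml_attr(s, "compartment")
    if (!is.na(cmp) && !cmp %in% comp_ids) {
      say("species '%s' references undefined compartment '%s'",
          xml2::xml_attr(s, "id"), cmp)
    }
  }
  for (p in params) {
    if (is.na(xml2::xml_attr(p, "constant"))) {
      say("parameter '%s' lacks required attribute 'constant'",
          xml2::xml_attr(p, "id"))
    }
  }

  constant_of <- c(stats::setNames(attr_of(species, "constant"), sp_ids),
                   stats::setNames(attr_of(params, "constant"), param_ids))
  boundary_of <- stats::setNames(attr_of(species, "boundaryCondition"), sp_ids)

  rule_vars <- attr_of(rules, "variable")
  for (v in rule_vars[duplicated(rule_vars)]) {
    say("more than one rule assigns variable '%s'", v)
  }
  for (v in rule_vars) {
    if (is.na(v) || !v %in% c(sp_ids, param_ids, comp_ids)) {
      say("assignment rule targets undefined variable '%s'", v)
    } else if (identical(constant_of[[v]], "true")) {
      say("assignment rule targets constant entity '%s'", v)
    }
  }

  defined_symbols <- c(comp_ids, sp_ids, param_ids)
  check_ci <- function(node, what) {
    cis <- xml2::xml_text(xml2::xml_find_all(
      node, ".//*[local-name() = 'ci']"))
    for (sym in trimws(cis)) {
      if (!sym %in% defined_symbols) {
        say("%s references undefined symbol '%s'", what, sym)
      }
    }
  }
  for (r in rules) check_ci(r, sprintf("rule for '%s'", xml2::xml_attr(r, "variable")))

  for (rx in reactions) {
    rid <- xml2::xml_attr(rx, "id")
    for (a in c("reversible", "fast")) {
      if (is.na(xml2::xml_attr(rx, a))) {
        say("reaction '%s' lacks required attribute '%s'", rid, a)
      }
    }
    refs <- xml2::xml_find_all(rx, ".//s:speciesReference", ns)
    for (ref in refs) {
      sref <- xml2::xml_attr(ref, "species")
      if (is.na(sref) || !sref %in% sp_ids) {
        say("reaction '%s' references undefined species '%s'", rid, sref)
      } else if (identical(boundary_of[[sref]], "false") &&
                 sref %in% rule_vars) {
        say("reaction '%s' consumes/produces rule-governed species '%s' without boundaryCondition",
            rid, sref)
      }
      if (is.na(xml2::xml_attr(ref, "constant"))) {
        say("species reference in reaction '%s' lacks required attribute 'constant'", rid)
      }
    }
    mods <- xml2::xml_find_all(rx, ".//s:modifierSpeciesReference", ns)
    for (m in mods) {
      sref <- xml2::xml_attr(m, "species")
      if (is.na(sref) || !sref %in% sp_ids) {
        say("reaction '%s' has modifier referencing undefined species '%s'",
            rid, sref)
      }
    }
    kl <- xml2::xml_find_first(rx, ".//s:kineticLaw", ns)
    if (!inherits(kl, "xml_missing")) {
      check_ci(kl, sprintf("kinetic law of reaction '%s'", rid))
    }
  }
  errs
}
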