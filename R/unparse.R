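# Canonical text rendering of AST nodes and models. parse_model() of the
# rendered text is structurally equal to what was rendered (positions
# aside); state-list order is preserved verbatim, nothing is sorted.

PRECEDENCE <- c("+" = 1, "-" = 1, "*" = 2, "/" = 2, "^" = 3)

#' Render an expression AST as text
#'
#' @param expr an expression node.
#' @return a single string; parentheses are inserted only where needed.
#' @export
expr_text <- function(expr) {
  # min_prec: parenthesize this node if its own precedence is lower.
  # Operands are rendered with the exact precedence floor that keeps the
  # reparsed tree identical (the parser is left-associative for + - * /
  # and right-associative for ^).
  render <- function(e, min_prec) {
    switch(e$kind,
      num = format_num(e$value),
      ident = e$name,
      accessor = paste0(e$species, ".", e$site),
      call = paste0(e$fn, "(",
                    paste(vapply(e$args, function(a) render(a, 0),
                                 character(1)), collapse = ", "), ")"),
      sum = sum_text(e),
      neg = {
        txt <- paste0("-", render(e$arg, 4))
        if (min_prec > 3.5) paste0("(", txt, ")") else txt
      },
      binop = {
        p <- PRECEDENCE[[e$op]]
        if (e$op == "^") {
          txt <- paste(render(e$lhs, p + 0.5), e$op, render(e$rhs, p))
        } else {
          txt <- paste(render(e$lhs, p), e$op, render(e$rhs, p + 0.5))
        }
        if (p < min_prec) paste0("(", txt, ")") else txt
      },
      stop("unknown expression kind: ", e$kind))
  }
  render(expr, 0)
}

sum_text <- function(e) {
  parts <- e$species
  for (r in e$restr) parts <- c(parts, paste0(r$site, states_text(r)))
  if (!is.null(e$weight)) parts <- c(parts, expr_text(e$weight))
  paste0("SUM(", paste(parts, collapse = ";"), ")")
}

states_text <- function(spec) {
  switch(spec$kind,
    range = paste0("{", expr_text(spec$lo), ":", expr_text(spec$hi), "}"),
    enumset = paste0("{", paste(spec$labels, collapse = ","), "}"),
    fixed = paste0("{", spec$label, "}"),
    empty = "",
    stop("unknown state spec kind: ", spec$kind))
}

site_def_text <- function(site) {
  paste0(site$name, states_text(site), if (isTRUE(site$circular)) "~circ" else "")
}

#' @rdname unparse
#' @export
species_def_text <- function(def) {
  if (length(def$sites) == 0) return(def$name)
  paste0(def$name, "(",
         paste(vapply(def$sites, site_def_text, character(1)), collapse = ", "),
         ")")
}

pattern_text <- function(site_name, pat) {
  switch(pat$kind,
    any = site_name,
    fixed = paste0(site_name, "{", pat$label, "}"),
    range = paste0(site_name, "{", expr_text(pat$lo), ":", expr_text(pat$hi), "}"),
    enumset = paste0(site_name, "{", paste(pat$labels, collapse = ","), "}"),
    opcall = paste0(pat$op, "(", pat$site, ")"),
    transfer = paste0(site_name, "=",
                      if (is.null(pat$op)) paste0(pat$src_species, ".", pat$src_site)
                      else paste0(pat$op, "(", pat$src_species, ".", pat$src_site, ")")),
    stop("unknown pattern kind: ", pat$kind))
}

#' @rdname unparse
#' @export
species_ref_text <- function(ref) {
  if (length(ref$patterns) == 0) return(ref$species)
  pats <- vapply(seq_along(ref$patterns), function(i) {
    pattern_text(names(ref$patterns)[[i]], ref$patterns[[i]])
  }, character(1))
  paste0(ref$species, "(", paste(pats, collapse = ", "), ")")
}

side_text <- function(refs) {
  paste(vapply(refs, species_ref_text, character(1)), collapse = " + ")
}

rate_text <- function(rate) {
  if (is.null(rate)) return("")
  switch(rate$kind,
    rate_ma = paste0(" | MA : ", expr_text(rate$rate)),
    rate_ud = paste0(" | UD : ", expr_text(rate$call)),
    rate_k = paste0(" | K : ", expr_text(rate$expr)))
}

#' @rdname unparse
#' @export
reaction_text <- function(rxn, with_rate = TRUE, with_name = FALSE) {
  txt <- paste0(side_text(rxn$reactants), " -> ", side_text(rxn$products))
  if (length(rxn$modifiers)) txt <- paste0(txt, "; ", side_text(rxn$modifiers))
  if (with_rate) txt <- paste0(txt, rate_text(rxn$rate))
  if (with_name && !is.null(rxn$name)) txt <- paste0(rxn$name, " : ", txt)
  txt
}

#' Render a model (or model AST) back to canonical .msl text
#'
#' The inverse of [parse_model()]: `parse_model(unparse(x))` is
#' structurally equal to `x`. Entries that failed to parse are written
#' back verbatim in their original section, so a model carrying errors is
#' saved without loss. Reactions and species generated from complex
#' declarations are not written (they are regenerated on load).
#'
#' @param x a `model_ast` from [parse_model()] or a built `msl_model`.
#' @return a single string of .msl text.
#' @export
unparse <- function(x) {
  if (inherits(x, "msl_model")) x <- model_to_ast(x)
  out <- character()
  emit_section <- function(header, entries, raws) {
    if (length(entries) == 0 && length(raws) == 0) return()
    out[[length(out) + 1L]] <<- paste0("[", header, "]")
    for (e in entries) out[[length(out) + 1L]] <<- e
    for (r in raws) out[[length(out) + 1L]] <<- r
    out[[length(out) + 1L]] <<- ""
  }
  raw_in <- function(section) {
    vapply(Filter(function(r) identical(r$section, section), x$raw),
           `[[`, "", "text")
  }
  emit_section("species", vapply(x$species, function(sp) {
    txt <- species_def_text(sp$def)
    if (!is.null(sp$assignment)) paste0(txt, " := ", expr_text(sp$assignment))
    else if (!is.null(sp$initial)) paste0(txt, " = ", expr_text(sp$initial))
    else txt
  }, character(1)), raw_in("species"))
  emit_section("globals", vapply(x$globals, function(g) {
    paste0(g$name, if (g$role == "assigned") " := " else " = ", expr_text(g$expr))
  }, character(1)), raw_in("globals"))
  emit_section("functions", vapply(x$functions, function(f) {
    params <- paste(vapply(f$params, function(p) paste(p$role, p$name),
                           character(1)), collapse = ", ")
    paste0(f$name, "(", params, ") = ", expr_text(f$body))
  }, character(1)), raw_in("functions"))
  emit_section("reactions", vapply(x$reactions, function(r) {
    reaction_text(r, with_rate = TRUE, with_name = TRUE)
  }, character(1)), raw_in("reactions"))
  emit_section("complexes", vapply(x$complexes, function(cx) {
    txt <- paste(vapply(cx$components, species_ref_text, character(1)),
                 collapse = " + ")
    if (!is.null(cx$name)) txt <- paste0(cx$name, " : ", txt)
    if (isTRUE(cx$generate_reactions)) txt <- paste0(txt, " | reactions")
    txt
  }, character(1)), raw_in("complexes"))
  emit_section("initials", vapply(x$initials, function(iv) {
    paste0(species_ref_text(iv$ref), " = ", expr_text(iv$value))
  }, character(1)), raw_in("initials"))
  paste(out, collapse = "\n")
}

#' Write a model to a .msl file
#'
#' @param x a model or model AST.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_msl <- function(x, path) {
  writeLines(unparse(x), path, useBytes = TRUE)
  invisible(path)
}

#' Compare two parsed models structurally
#'
#' Equality of [parse_model()] results up to source positions and
#' diagnostic locations (line numbers change when a model is re-rendered;
#' the structure must not).
#'
#' @param a,b `model_ast` objects.
#' @return `TRUE` or `FALSE`.
#' @export
ast_equal <- function(a, b) {
  canon <- function(x) {
    x$diagnostics <- NULL
    x$raw <- lapply(x$raw, function(r) r[c("section", "text")])
    strip_pos(x)
  }
  identical(canon(a), canon(b))
}
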