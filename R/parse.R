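# Recursive-descent parser for the multistate model language.
#
# Grammar sketch (whitespace insignificant inside constructs):
#   species_def : NAME [ '(' site_def (',' site_def)* ')' ]
#   site_def    : NAME [ '{' states '}' ] [ '~' 'circ' ]
#   states      : expr ':' expr | label (',' label)*
#   reaction    : side '->' side [ ';' mod_refs ] [ '|' rate ]
#   side        : [ ref ('+' ref)* ]
#   ref         : NAME [ '(' pat (',' pat)* ')' ]
#   pat         : NAME '{' states '}'            fixed / range / enum subset
#               | ('succ'|'pred') '(' NAME ')'   operator on a reactant site
#               | NAME '=' transfer_rhs          transfer of state
#               | NAME                           unconstrained site
#   transfer_rhs: [('succ'|'pred') '('] NAME '.' NAME [')']
#   rate        : 'MA' ':' expr | 'UD' ':' call
#   expr        : usual arithmetic with calls, NAME '.' NAME accessors and
#                 SUM(species; restrictions...; weight)

# ---------------------------------------------------------------- expressions

parse_expr_ts <- function(ts) {
  lhs <- parse_term_ts(ts)
  while (ts_at(ts, "+") || ts_at(ts, "-")) {
    op <- ts_next(ts)
    rhs <- parse_term_ts(ts)
    lhs <- e_binop(op$value, lhs, rhs, pos = tok_pos(op))
  }
  lhs
}

parse_term_ts <- function(ts) {
  lhs <- parse_power_ts(ts)
  while (ts_at(ts, "*") || ts_at(ts, "/")) {
    op <- ts_next(ts)
    rhs <- parse_power_ts(ts)
    lhs <- e_binop(op$value, lhs, rhs, pos = tok_pos(op))
  }
  lhs
}

parse_power_ts <- function(ts) {
  base <- parse_unary_ts(ts)
  if (ts_at(ts, "^")) {
    op <- ts_next(ts)
    # right-associative
    e_binop("^", base, parse_power_ts(ts), pos = tok_pos(op))
  } else {
    base
  }
}

parse_unary_ts <- function(ts) {
  if (ts_at(ts, "-")) {
    op <- ts_next(ts)
    return(e_neg(parse_unary_ts(ts), pos = tok_pos(op)))
  }
  parse_primary_ts(ts)
}

parse_primary_ts <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) msl_parse_error("expected expression", ts$line, NA_integer_)
  if (tok$type == "num") {
    ts_next(ts)
    return(e_num(as.numeric(tok$value), pos = tok_pos(tok)))
  }
  if (ts_at(ts, "(")) {
    ts_next(ts)
    inner <- parse_expr_ts(ts)
    ts_expect(ts, ")")
    return(inner)
  }
  if (tok$type == "ident") {
    ts_next(ts)
    if (tok$value == "SUM" && ts_at(ts, "(")) {
      return(parse_sum_ts(ts, pos = tok_pos(tok)))
    }
    if (ts_at(ts, "(")) {
      ts_next(ts)
      args <- list()
      if (!ts_at(ts, ")")) {
        repeat {
          args[[length(args) + 1L]] <- parse_expr_ts(ts)
          if (ts_at(ts, ",")) { ts_next(ts); next }
          break
        }
      }
      ts_expect(ts, ")")
      return(e_call(tok$value, args, pos = tok_pos(tok)))
    }
    if (ts_at(ts, ".")) {
      ts_next(ts)
      site <- ts_expect_ident(ts, "site name after '.'")
      return(e_accessor(tok$value, site$value, pos = tok_pos(tok)))
    }
    return(e_ident(tok$value, pos = tok_pos(tok)))
  }
  msl_parse_error(sprintf("unexpected token '%s' in expression", tok$value),
                  tok$line, tok$col)
}

parse_sum_ts <- function(ts, pos) {
  ts_expect(ts, "(")
  sp <- ts_expect_ident(ts, "species name in SUM")
  restr <- list()
  weight <- NULL
  while (ts_at(ts, ";")) {
    ts_next(ts)
    nxt <- ts_peek(ts)
    if (!is.null(nxt) && nxt$type == "ident" && ts_at(ts, "{", offset = 1L)) {
      if (!is.null(weight)) {
        msl_parse_error("SUM weight must be the last segment", nxt$line, nxt$col)
      }
      site <- ts_next(ts)
      spec <- parse_states_ts(ts, allow_range = TRUE)
      if (spec$kind == "fixed") spec <- list(kind = "enumset", labels = spec$label)
      restr[[length(restr) + 1L]] <- c(list(site = site$value), spec)
    } else {
      if (!is.null(weight)) {
        msl_parse_error("SUM accepts at most one weight expression",
                        if (is.null(nxt)) ts$line else nxt$line,
                        if (is.null(nxt)) NA_integer_ else nxt$col)
      }
      weight <- parse_expr_ts(ts)
    }
  }
  ts_expect(ts, ")")
  sites <- vapply(restr, function(r) r$site, character(1))
  if (anyDuplicated(sites)) {
    msl_parse_error(sprintf("duplicate SUM restriction for site '%s'",
                            sites[duplicated(sites)][1]), pos[1], pos[2])
  }
  e_sum(sp$value, restr, weight, pos = pos)
}

# Content between '{' and '}': either a range (expr ':' expr) or a
# comma-separated label list. Returns list(kind=..., ...), braces consumed.
parse_states_ts <- function(ts, allow_range = TRUE) {
  open <- ts_expect(ts, "{")
  if (ts_at(ts, "}")) {
    msl_parse_error("empty state list", open$line, open$col)
  }
  first <- parse_expr_ts(ts)
  if (ts_at(ts, ":")) {
    if (!allow_range) {
      tok <- ts_peek(ts)
      msl_parse_error("range not allowed here", tok$line, tok$col)
    }
    ts_next(ts)
    hi <- parse_expr_ts(ts)
    ts_expect(ts, "}")
    return(list(kind = "range", lo = first, hi = hi))
  }
  labels <- expr_to_label(first)
  while (ts_at(ts, ",")) {
    ts_next(ts)
    labels <- c(labels, expr_to_label(parse_expr_ts(ts)))
  }
  ts_expect(ts, "}")
  if (length(labels) == 1L) list(kind = "fixed", label = labels)
  else list(kind = "enumset", labels = labels)
}

# A state label is a bare number or identifier.
expr_to_label <- function(expr) {
  if (identical(expr$kind, "num")) return(format_num(expr$value))
  if (identical(expr$kind, "ident")) return(expr$name)
  if (identical(expr$kind, "neg") && identical(expr$arg$kind, "num")) {
    return(paste0("-", format_num(expr$arg$value)))
  }
  p <- node_pos(expr)
  msl_parse_error("state label must be a number or a name", p[1], p[2])
}

format_num <- function(x) {
  if (is.finite(x) && x == round(x) && abs(x) < 1e15) {
    format(as.integer(x) * 1, scientific = FALSE)
  } else {
    format(x, scientific = FALSE, trim = TRUE)
  }
}

# ------------------------------------------------------------- species defs

parse_species_def_ts <- function(ts) {
  nm <- ts_expect_ident(ts, "species name")
  sites <- list()
  if (ts_at(ts, "(")) {
    ts_next(ts)
    repeat {
      site_tok <- ts_expect_ident(ts, "site name")
      site <- list(name = site_tok$value, kind = "empty",
                   circular = FALSE)
      if (ts_at(ts, "{")) {
        spec <- parse_states_ts(ts, allow_range = TRUE)
        if (spec$kind == "fixed") spec <- list(kind = "enumset", labels = spec$label)
        site$kind <- spec$kind
        if (spec$kind == "range") { site$lo <- spec$lo; site$hi <- spec$hi }
        else site$labels <- spec$labels
      }
      if (ts_at(ts, "~")) {
        ts_next(ts)
        flag <- ts_expect_ident(ts, "'circ' flag")
        if (flag$value != "circ") {
          msl_parse_error(sprintf("unknown site flag '~%s'", flag$value),
                          flag$line, flag$col)
        }
        site$circular <- TRUE
      }
      attr(site, "pos") <- tok_pos(site_tok)
      if (site$name %in% vapply(sites, `[[`, "", "name")) {
        msl_parse_error(sprintf("duplicate site name '%s'", site$name),
                        site_tok$line, site_tok$col)
      }
      if (identical(site$kind, "enumset") && anyDuplicated(site$labels)) {
        msl_parse_error(sprintf("duplicate state label in site '%s'", site$name),
                        site_tok$line, site_tok$col)
      }
      sites[[length(sites) + 1L]] <- site
      if (ts_at(ts, ",")) { ts_next(ts); next }
      break
    }
    ts_expect(ts, ")")
  }
  node("species_def", name = nm$value, sites = sites, pos = tok_pos(nm))
}

#' Parse a multistate species definition
#'
#' Accepts the compact site syntax: integer ranges (`Cdh1(p{0:10})`,
#' bounds may be arithmetic over fixed global quantities), enumerated
#' state lists (`S(s1{free,bound,hidden})`), the circular marker
#' (`s(p{0:3}~circ)`) and zero-site species (`ClbM`).
#'
#' @param text a single species definition.
#' @return a `species_def` AST node with fields `name` and `sites`; each
#'   site has `name`, `kind` (`"range"`, `"enumset"` or `"empty"`),
#'   bounds or labels, and a `circular` flag.
#' @examples
#' parse_species("Cdh1(p{0:10})")
#' parse_species("S(s1{free,bound,hidden}, s2{2,4,6,8,0})")
#' @export
parse_species <- function(text) {
  ts <- token_stream(msl_tokenize(text))
  out <- parse_species_def_ts(ts)
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  out
}

# ------------------------------------------------------------- species refs

parse_species_ref_ts <- function(ts, in_products = FALSE) {
  nm <- ts_expect_ident(ts, "species name")
  patterns <- list()
  if (ts_at(ts, "(")) {
    ts_next(ts)
    repeat {
      tok <- ts_expect_ident(ts, "site name or operator")
      if (tok$value %in% c("succ", "pred") && ts_at(ts, "(")) {
        ts_next(ts)
        site <- ts_expect_ident(ts, "site name")
        ts_expect(ts, ")")
        pat <- node("opcall", op = tok$value, site = site$value,
                    pos = tok_pos(tok))
        key <- site$value
      } else if (ts_at(ts, "{")) {
        spec <- parse_states_ts(ts, allow_range = TRUE)
        pat <- do.call(node, c(list(spec$kind),
                               spec[setdiff(names(spec), "kind")],
                               list(pos = tok_pos(tok))))
        key <- tok$value
      } else if (ts_at(ts, "=")) {
        ts_next(ts)
        pat <- parse_transfer_rhs_ts(ts, pos = tok_pos(tok))
        key <- tok$value
      } else {
        pat <- node("any", pos = tok_pos(tok))
        key <- tok$value
      }
      if (key %in% names(patterns)) {
        msl_parse_error(sprintf("site '%s' constrained twice", key),
                        tok$line, tok$col)
      }
      patterns[[key]] <- pat
      if (ts_at(ts, ",")) { ts_next(ts); next }
      break
    }
    ts_expect(ts, ")")
  }
  node("species_ref", species = nm$value, patterns = patterns,
       pos = tok_pos(nm))
}

parse_transfer_rhs_ts <- function(ts, pos) {
  tok <- ts_expect_ident(ts, "transfer source")
  op <- NULL
  if (tok$value %in% c("succ", "pred") && ts_at(ts, "(")) {
    op <- tok$value
    ts_next(ts)
    tok <- ts_expect_ident(ts, "source species")
  }
  ts_expect(ts, ".")
  site <- ts_expect_ident(ts, "source site")
  if (!is.null(op)) ts_expect(ts, ")")
  node("transfer", src_species = tok$value, src_site = site$value,
       op = op, pos = pos)
}

# ---------------------------------------------------------------- reactions

parse_reaction_ts <- function(ts, name = NULL) {
  pos <- if (ts_eof(ts)) c(NA_integer_, NA_integer_) else tok_pos(ts_peek(ts))
  reactants <- parse_side_ts(ts, stop_at = "->")
  ts_expect(ts, "->")
  products <- parse_side_ts(ts, stop_at = c(";", "|"))
  modifiers <- list()
  if (ts_at(ts, ";")) {
    ts_next(ts)
    modifiers <- parse_side_ts(ts, stop_at = "|", allow_comma = TRUE)
  }
  rate <- NULL
  if (ts_at(ts, "|")) {
    ts_next(ts)
    rate <- parse_rate_ts(ts)
  }
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  node("reaction", name = name, reactants = reactants, products = products,
       modifiers = modifiers, rate = rate, pos = pos)
}

parse_side_ts <- function(ts, stop_at, allow_comma = FALSE) {
  refs <- list()
  if (ts_eof(ts) || any(vapply(stop_at, ts_at, TRUE, ts = ts))) return(refs)
  repeat {
    refs[[length(refs) + 1L]] <- parse_species_ref_ts(ts)
    if (ts_at(ts, "+") || (allow_comma && ts_at(ts, ","))) {
      ts_next(ts)
      next
    }
    break
  }
  refs
}

parse_rate_ts <- function(ts) {
  tok <- ts_expect_ident(ts, "rate-law type (MA, UD or K)")
  if (!tok$value %in% c("MA", "UD", "K")) {
    msl_parse_error(sprintf("unknown rate-law type '%s' (expected MA, UD or K)",
                            tok$value), tok$line, tok$col)
  }
  ts_expect(ts, ":")
  expr <- parse_expr_ts(ts)
  if (tok$value == "MA") {
    node("rate_ma", rate = expr, pos = tok_pos(tok))
  } else if (tok$value == "K") {
    # explicit kinetic formula, used by the flat .msl dialect
    node("rate_k", expr = expr, pos = tok_pos(tok))
  } else {
    if (!identical(expr$kind, "call")) {
      msl_parse_error("UD rate law must be a function call", tok$line, tok$col)
    }
    node("rate_ud", call = expr, pos = tok_pos(tok))
  }
}

#' Parse a multistate reaction
#'
#' The two sides are separated by `->`; stoichiometry is expressed by
#' repetition. Modifier references follow a `;` after the products, as in
#' `R(c{1:d}) -> P1(c=succ(R.c)) + P2; M(c=R.c)`. An optional rate-law
#' tag follows a `|`: either `| MA : k` (mass action with rate constant
#' `k`) or `| UD : fn(args...)` (a user-defined rate function).
#'
#' @param text a single reaction.
#' @param name optional reaction identifier.
#' @return a `reaction` AST node with `reactants`, `products`,
#'   `modifiers` (lists of species references) and `rate`.
#' @examples
#' parse_reaction("Cdh1(p{0:9}) + ClbM -> Cdh1(succ(p)) + ClbM")
#' parse_reaction("-> A")
#' @export
parse_reaction <- function(text, name = NULL) {
  parse_reaction_ts(token_stream(msl_tokenize(text)), name = name)
}

#' Parse an arithmetic expression
#'
#' Standard operator precedence over numbers, identifiers, function
#' calls, `species.site` accessors, and the `SUM` aggregate
#' (`SUM(species; site{lo:hi}; weight)`, restrictions and weight
#' optional).
#'
#' @param text a single expression.
#' @return an expression AST node.
#' @examples
#' parse_expression("SUM(Cdh1;p{1:10})")
#' parse_expression("(N-i)*k*X*K")
#' @export
parse_expression <- function(text) {
  ts <- token_stream(msl_tokenize(text))
  out <- parse_expr_ts(ts)
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  out
}
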