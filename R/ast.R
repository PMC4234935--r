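# Abstract syntax tree node constructors and generic tree utilities.
#
# Every node is a plain list with a `kind` field; positions (line/col)
# travel in the "pos" attribute so that structural comparison can ignore
# them. Expression kinds: num, ident, accessor, call, binop, neg, sum.

node <- function(kind, ..., pos = NULL) {
  n <- c(list(kind = kind), list(...))
  if (!is.null(pos)) attr(n, "pos") <- pos
  n
}

e_num <- function(value, pos = NULL) node("num", value = value, pos = pos)
e_ident <- function(name, pos = NULL) node("ident", name = name, pos = pos)
e_accessor <- function(species, site, pos = NULL)
  node("accessor", species = species, site = site, pos = pos)
e_call <- function(fn, args, pos = NULL) node("call", fn = fn, args = args, pos = pos)
e_binop <- function(op, lhs, rhs, pos = NULL)
  node("binop", op = op, lhs = lhs, rhs = rhs, pos = pos)
e_neg <- function(arg, pos = NULL) node("neg", arg = arg, pos = pos)

# SUM(species; restrictions...; weight). restr: list of
# list(site=, kind="range", lo=, hi=) or list(site=, kind="enumset", labels=)
e_sum <- function(species, restr = list(), weight = NULL, pos = NULL)
  node("sum", species = species, restr = restr, weight = weight, pos = pos)

node_pos <- function(n) {
  p <- attr(n, "pos")
  if (is.null(p)) c(NA_integer_, NA_integer_) else p
}

tok_pos <- function(tok) c(tok$line, tok$col)

#' Strip source positions from an AST
#'
#' Removes the line/column annotations from every node so that two parses
#' of equivalent text compare equal with [identical()].
#'
#' @param x any AST node, model, or list of nodes.
#' @return the same structure without position attributes.
#' @export
strip_pos <- function(x) {
  if (is.list(x)) {
    attr(x, "pos") <- NULL
    out <- lapply(x, strip_pos)
    attributes(out) <- attributes(x)[setdiff(names(attributes(x)), c("pos", "names"))]
    names(out) <- names(x)
    out
  } else {
    x
  }
}

# Walk an expression tree, calling fn on every node (pre-order).
expr_walk <- function(expr, fn) {
  if (!is.list(expr) || is.null(expr$kind)) return(invisible(NULL))
  fn(expr)
  switch(expr$kind,
    binop = { expr_walk(expr$lhs, fn); expr_walk(expr$rhs, fn) },
    neg = expr_walk(expr$arg, fn),
    call = for (a in expr$args) expr_walk(a, fn),
    sum = {
      for (r in expr$restr) {
        if (identical(r$kind, "range")) { expr_walk(r$lo, fn); expr_walk(r$hi, fn) }
      }
      if (!is.null(expr$weight)) expr_walk(expr$weight, fn)
    },
    NULL)
  invisible(NULL)
}

# Transform an expression bottom-up; fn receives each node and returns a
# (possibly new) node.
expr_map <- function(expr, fn) {
  if (!is.list(expr) || is.null(expr$kind)) return(expr)
  out <- switch(expr$kind,
    binop = { expr$lhs <- expr_map(expr$lhs, fn); expr$rhs <- expr_map(expr$rhs, fn); expr },
    neg = { expr$arg <- expr_map(expr$arg, fn); expr },
    call = { expr$args <- lapply(expr$args, expr_map, fn = fn); expr },
    sum = {
      expr$restr <- lapply(expr$restr, function(r) {
        if (identical(r$kind, "range")) {
          r$lo <- expr_map(r$lo, fn); r$hi <- expr_map(r$hi, fn)
        }
        r
      })
      if (!is.null(expr$weight)) expr$weight <- expr_map(expr$weight, fn)
      expr
    },
    expr)
  fn(out)
}

# All identifier names appearing free in an expression (not function names,
# not accessor parts -- those are reported separately).
expr_idents <- function(expr) {
  acc <- character()
  expr_walk(expr, function(n) {
    if (identical(n$kind, "ident")) acc[[length(acc) + 1L]] <<- n$name
  })
  unique(acc)
}
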