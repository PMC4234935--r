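# Document-level parsing of the sectioned .msl format.
#
# A model file is plain UTF-8 text divided into sections by bracketed
# headers mirroring the tabs of a spreadsheet model editor:
#
#   [species]    Cdh1(p{0:10}) = 1        definition = default initial
#                M(c) := SUM(R;c{M.c+1:M.c+14})   assigned species
#   [reactions]  r1 : Cdh1(p{0:9}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : kp
#   [globals]    maxP = 10                fixed;  total := SUM(Cdh1)  assigned
#   [functions]  dis(GLQ N, SITE i, GLQ k, SUB X, SUB K) = (N-i)*k*X*K
#   [complexes]  Net1_Cdc14 : Net1(p{0:5}) + Cdc14 | reactions
#   [initials]   Cdh1(p{0}) = 5           per-state override
#
# '#' starts a comment; blank lines are ignored. One malformed line does
# not abort the file: the entry is kept verbatim (so the model can be
# saved again unchanged) and a parse diagnostic is recorded.

MSL_SECTIONS <- c("species", "reactions", "globals", "functions",
                  "complexes", "initials")

#' Parse a model document
#'
#' @param document the model text: a single string (possibly with
#'   newlines) or a character vector of lines.
#' @return a `model_ast` object: lists `species`, `reactions`, `globals`,
#'   `functions`, `complexes`, `initials`, verbatim `raw` entries for
#'   lines that failed to parse, and `diagnostics` (a list of
#'   [msl_issue()] objects, one per malformed entry).
#' @seealso [read_msl()] to go straight to a validated model,
#'   [unparse()] for the inverse.
#' @export
parse_model <- function(document) {
  lines <- if (length(document) == 1L && grepl("\n", document)) {
    strsplit(document, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(document)
  }
  ast <- list(kind = "model_ast", species = list(), reactions = list(),
              globals = list(), functions = list(), complexes = list(),
              initials = list(), raw = list(), diagnostics = list())
  class(ast) <- "msl_ast"
  section <- NA_character_
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    if (!nzchar(trimws(line))) next
    header <- regmatches(line, regexec("^\\s*\\[\\s*([A-Za-z]+)\\s*\\]\\s*$", line))[[1]]
    if (length(header) == 2L) {
      sec <- tolower(header[2])
      if (!sec %in% MSL_SECTIONS) {
        ast$diagnostics[[length(ast$diagnostics) + 1L]] <-
          msl_issue("error", "unknown_section",
                    sprintf("unknown section '[%s]'", sec), i)
        section <- NA_character_
      } else {
        section <- sec
      }
      next
    }
    if (is.na(section)) {
      ast$diagnostics[[length(ast$diagnostics) + 1L]] <-
        msl_issue("error", "no_section",
                  "entry appears before any section header", i)
      ast$raw[[length(ast$raw) + 1L]] <-
        list(section = NA_character_, text = lines[[i]], line = i)
      next
    }
    res <- tryCatch(
      parse_entry(trimws(line), section, i),
      msl_parse_error = function(e) e
    )
    if (inherits(res, "msl_parse_error")) {
      ast$diagnostics[[length(ast$diagnostics) + 1L]] <-
        msl_issue("error", "parse_error",
                  sprintf("[%s] %s", section, conditionMessage(res)), i)
      ast$raw[[length(ast$raw) + 1L]] <-
        list(section = section, text = trimws(lines[[i]]), line = i)
    } else {
      ast[[res$slot]][[length(ast[[res$slot]]) + 1L]] <- res$entry
    }
  }
  ast
}

# Parse one entry line within a known section.
parse_entry <- function(text, section, line) {
  toks <- msl_tokenize(text, line)
  ts <- token_stream(toks, line)
  switch(section,
    species = list(slot = "species", entry = parse_species_entry(ts)),
    reactions = list(slot = "reactions", entry = parse_reaction_entry(ts)),
    globals = list(slot = "globals", entry = parse_global_entry(ts)),
    functions = list(slot = "functions", entry = parse_function_entry(ts)),
    complexes = list(slot = "complexes", entry = parse_complex_entry(ts)),
    initials = list(slot = "initials", entry = parse_initial_entry(ts))
  )
}

# Position of the first depth-0 occurrence of an op value, or NA.
find_top_level <- function(toks, values) {
  depth <- 0L
  for (i in seq_along(toks)) {
    t <- toks[[i]]
    if (t$type == "op") {
      if (t$value %in% c("(", "{")) depth <- depth + 1L
      else if (t$value %in% c(")", "}")) depth <- depth - 1L
      else if (depth == 0L && t$value %in% values) return(i)
    }
  }
  NA_integer_
}

parse_species_entry <- function(ts) {
  def <- parse_species_def_ts(ts)
  initial <- NULL
  assignment <- NULL
  if (ts_at(ts, ":=")) {
    ts_next(ts)
    assignment <- parse_expr_ts(ts)
  } else if (ts_at(ts, "=")) {
    ts_next(ts)
    initial <- parse_expr_ts(ts)
  }
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  node("species_entry", def = def, initial = initial,
       assignment = assignment, pos = node_pos(def))
}

parse_reaction_entry <- function(ts) {
  name <- NULL
  first <- ts_peek(ts)
  if (!is.null(first) && first$type == "ident" && ts_at(ts, ":", offset = 1L)) {
    name <- ts_next(ts)$value
    ts_next(ts)  # ':'
  }
  parse_reaction_ts(ts, name = name)
}

parse_global_entry <- function(ts) {
  nm <- ts_expect_ident(ts, "global quantity name")
  role <- if (ts_at(ts, ":=")) "assigned" else "fixed"
  if (ts_at(ts, ":=") || ts_at(ts, "=")) ts_next(ts)
  else {
    tok <- ts_peek(ts)
    msl_parse_error("expected '=' or ':=' after global quantity name",
                    if (is.null(tok)) nm$line else tok$line,
                    if (is.null(tok)) NA_integer_ else tok$col)
  }
  expr <- parse_expr_ts(ts)
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  node("global", name = nm$value, role = role, expr = expr, pos = tok_pos(nm))
}

parse_function_entry <- function(ts) {
  nm <- ts_expect_ident(ts, "function name")
  ts_expect(ts, "(")
  params <- list()
  if (!ts_at(ts, ")")) {
    repeat {
      role <- ts_expect_ident(ts, "parameter role (GLQ, SITE or SUB)")
      if (!role$value %in% c("GLQ", "SITE", "SUB")) {
        msl_parse_error(sprintf("unknown parameter role '%s'", role$value),
                        role$line, role$col)
      }
      pname <- ts_expect_ident(ts, "parameter name")
      params[[length(params) + 1L]] <- list(name = pname$value, role = role$value)
      if (ts_at(ts, ",")) { ts_next(ts); next }
      break
    }
  }
  ts_expect(ts, ")")
  ts_expect(ts, "=")
  body <- parse_expr_ts(ts)
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  node("function_def", name = nm$value, params = params, body = body,
       pos = tok_pos(nm))
}

parse_complex_entry <- function(ts) {
  name <- NULL
  first <- ts_peek(ts)
  if (!is.null(first) && first$type == "ident" && ts_at(ts, ":", offset = 1L)) {
    name <- ts_next(ts)$value
    ts_next(ts)  # ':'
  }
  components <- list()
  repeat {
    components[[length(components) + 1L]] <- parse_species_ref_ts(ts)
    if (ts_at(ts, "+")) { ts_next(ts); next }
    break
  }
  gen <- FALSE
  if (ts_at(ts, "|")) {
    ts_next(ts)
    flag <- ts_expect_ident(ts, "'reactions' flag")
    if (flag$value != "reactions") {
      msl_parse_error(sprintf("unknown complex flag '%s'", flag$value),
                      flag$line, flag$col)
    }
    gen <- TRUE
  }
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  node("complex_decl", name = name, components = components,
       generate_reactions = gen,
       pos = if (is.null(first)) c(NA_integer_, NA_integer_) else tok_pos(first))
}

parse_initial_entry <- function(ts) {
  ref <- parse_species_ref_ts(ts)
  ts_expect(ts, "=")
  value <- parse_expr_ts(ts)
  if (!ts_eof(ts)) {
    tok <- ts_peek(ts)
    msl_parse_error(sprintf("unexpected trailing input '%s'", tok$value),
                    tok$line, tok$col)
  }
  for (p in ref$patterns) {
    if (!identical(p$kind, "fixed")) {
      pos <- node_pos(ref)
      msl_parse_error("per-state initial values require fixed states for every site",
                      pos[1], pos[2])
    }
  }
  node("initial_override", ref = ref, value = value, pos = node_pos(ref))
}

#' @export
print.msl_ast <- function(x, ...) {
  cat(sprintf(
    "<msl model AST> %d species, %d reactions, %d globals, %d functions, %d complexes\n",
    length(x$species), length(x$reactions), length(x$globals),
    length(x$functions), length(x$complexes)))
  if (length(x$diagnostics)) {
    cat(sprintf("  %d parse diagnostic(s)\n", length(x$diagnostics)))
  }
  invisible(x)
}
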