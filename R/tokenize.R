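# Lexer for the multistate model language (.msl).
#
# Identifiers may start with a digit as long as the token is not a pure
# number (protein names such as 80S or 40S_eIF3 are legal), so numeric
# literals with an exponent are matched first with a boundary lookahead.

TOK_PATTERNS <- list(
  list(type = "num",
       re = "^([0-9]+\\.[0-9]+([eE][+-]?[0-9]+)?|[0-9]+[eE][+-]?[0-9]+)(?![A-Za-z0-9_.])"),
  list(type = "ident", re = "^[0-9]+[A-Za-z_][A-Za-z0-9_]*"),
  list(type = "num",   re = "^[0-9]+(?![0-9])"),
  list(type = "ident", re = "^[A-Za-z_][A-Za-z0-9_]*"),
  list(type = "op",    re = "^(->|:=)"),
  list(type = "op",    re = "^[(){},;:+*/^=.|~-]")
)

#' Tokenize one line of multistate-language text
#'
#' @param text a single string (one logical line).
#' @param line line number used for token positions.
#' @return list of tokens, each `list(type, value, line, col)`; `type` is
#'   one of `"num"`, `"ident"`, `"op"`.
#' @keywords internal
msl_tokenize <- function(text, line = 1L) {
  toks <- list()
  col <- 1L
  rest <- text
  while (nzchar(rest)) {
    ws <- regmatches(rest, regexpr("^[ \t]+", rest))
    if (length(ws) == 1L) {
      col <- col + nchar(ws)
      rest <- substring(rest, nchar(ws) + 1L)
      next
    }
    matched <- FALSE
    for (p in TOK_PATTERNS) {
      m <- regmatches(rest, regexpr(p$re, rest, perl = TRUE))
      if (length(m) == 1L && nzchar(m)) {
        toks[[length(toks) + 1L]] <-
          list(type = p$type, value = m, line = line, col = col)
        col <- col + nchar(m)
        rest <- substring(rest, nchar(m) + 1L)
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      msl_parse_error(sprintf("unexpected character '%s'", substring(rest, 1, 1)),
                      line, col)
    }
  }
  toks
}

# Token stream with a cursor; parsers share one of these.
token_stream <- function(tokens, line = 1L) {
  env <- new.env(parent = emptyenv())
  env$tokens <- tokens
  env$pos <- 1L
  env$line <- line
  env
}

ts_peek <- function(ts, offset = 0L) {
  i <- ts$pos + offset
  if (i > length(ts$tokens)) NULL else ts$tokens[[i]]
}

ts_next <- function(ts) {
  tok <- ts_peek(ts)
  if (is.null(tok)) {
    msl_parse_error("unexpected end of input", ts$line, NA_integer_)
  }
  ts$pos <- ts$pos + 1L
  tok
}

ts_eof <- function(ts) ts$pos > length(ts$tokens)

# TRUE if the next token is an "op" with this exact value
ts_at <- function(ts, value, offset = 0L) {
  tok <- ts_peek(ts, offset)
  !is.null(tok) && tok$type == "op" && tok$value == value
}

ts_expect <- function(ts, value) {
  tok <- ts_peek(ts)
  if (is.null(tok)) {
    msl_parse_error(sprintf("expected '%s' but input ended", value),
                    ts$line, NA_integer_)
  }
  if (!(tok$type == "op" && tok$value == value)) {
    msl_parse_error(sprintf("expected '%s' but found '%s'", value, tok$value),
                    tok$line, tok$col)
  }
  ts_next(ts)
}

ts_expect_ident <- function(ts, what = "identifier") {
  tok <- ts_peek(ts)
  if (is.null(tok)) {
    msl_parse_error(sprintf("expected %s but input ended", what),
                    ts$line, NA_integer_)
  }
  if (tok$type != "ident") {
    msl_parse_error(sprintf("expected %s but found '%s'", what, tok$value),
                    tok$line, tok$col)
  }
  ts_next(ts)
}

# Structured parse error -> condition of class msl_parse_error
msl_parse_error <- function(message, line = NA_integer_, col = NA_integer_) {
  cond <- structure(
    class = c("msl_parse_error", "error", "condition"),
    list(message = sprintf("[%s:%s] %s",
                           ifelse(is.na(line), "?", line),
                           ifelse(is.na(col), "?", col), message),
         call = NULL, line = line, col = col, raw_message = message))
  stop(cond)
}

is_valid_ident <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) &&
    grepl("^([A-Za-z_][A-Za-z0-9_]*|[0-9]+[A-Za-z_][A-Za-z0-9_]*)$", x)
}
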