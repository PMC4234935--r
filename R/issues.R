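# Severity-graded diagnostics. A model carrying issues of any severity
# stays constructible and saveable; issues never abort construction.

#' Create a validation issue
#'
#' @param severity one of `"error"`, `"warning"`, `"info"`.
#' @param code short stable identifier for the check that fired.
#' @param message human-readable explanation.
#' @param line,col source location (NA when not applicable).
#' @return an object of class `msl_issue`.
#' @export
msl_issue <- function(severity = c("error", "warning", "info"),
                      code, message, line = NA_integer_, col = NA_integer_) {
  severity <- match.arg(severity)
  structure(list(severity = severity, code = code, message = message,
                 line = as.integer(line), col = as.integer(col)),
            class = "msl_issue")
}

#' @export
print.msl_issue <- function(x, ...) {
  loc <- if (is.na(x$line)) "" else sprintf(" [line %d%s]", x$line,
                                            if (is.na(x$col)) "" else sprintf(", col %d", x$col))
  cat(sprintf("%s (%s)%s: %s\n", toupper(x$severity), x$code, loc, x$message))
  invisible(x)
}

#' Tabulate a list of issues
#'
#' @param issues list of [msl_issue()] objects.
#' @return a data.frame with columns severity, code, line, col, message.
#' @export
issues_df <- function(issues) {
  if (length(issues) == 0) {
    return(data.frame(severity = character(), code = character(),
                      line = integer(), col = integer(),
                      message = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    severity = vapply(issues, `[[`, "", "severity"),
    code = vapply(issues, `[[`, "", "code"),
    line = vapply(issues, `[[`, 1L, "line"),
    col = vapply(issues, `[[`, 1L, "col"),
    message = vapply(issues, `[[`, "", "message"),
    stringsAsFactors = FALSE)
}

#' Serialize issues as JSON lines
#'
#' One JSON object per line with fields severity, code, line, column,
#' message -- the interchange format used by the command-line interface.
#'
#' @param issues list of [msl_issue()] objects.
#' @param path optional file; when `NULL` the lines are returned.
#' @return character vector of JSON lines, invisibly when written.
#' @export
issues_json <- function(issues, path = NULL) {
  lines <- vapply(issues, function(i) {
    jsonlite::toJSON(list(severity = i$severity, code = i$code,
                          line = i$line, column = i$col, message = i$message),
                     auto_unbox = TRUE, na = "null")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

has_errors <- function(issues) {
  any(vapply(issues, function(i) identical(i$severity, "error"), TRUE))
}

# Mutable collector used internally by build/validate.
issue_collector <- function() {
  env <- new.env(parent = emptyenv())
  env$issues <- list()
  env$add <- function(severity, code, message, line = NA, col = NA) {
    env$issues[[length(env$issues) + 1L]] <-
      msl_issue(severity, code, message, line, col)
  }
  env$add_at <- function(severity, code, message, pos) {
    env$add(severity, code, message, pos[1], pos[2])
  }
  env
}
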