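test_msl <- function(name) {
  path <- system.file("extdata", name, package = "flatreact")
  if (!nzchar(path)) stop("missing fixture file: ", name)
  path
}

ast_identical <- function(a, b) identical(strip_pos(a), strip_pos(b))

error_issues <- function(issues) {
  Filter(function(i) identical(i$severity, "error"), issues)
}

issue_codes <- function(issues) vapply(issues, `[[`, "", "code")

build_text <- function(lines, policy = "off") {
  build_model(parse_model(lines), policy = policy)
}
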