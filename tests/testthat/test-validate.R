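# Severity-graded consistency checks.

test_that("succ applied where the reactant range includes the last state is the range-coherence error", {
  res <- build_text(c("[globals]", "k = 1", "[species]", "Cdh1(p{0:10}) = 1",
                      "ClbM = 1", "[reactions]",
                      "r1 : Cdh1(p{0:10}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : k"))
  v <- validate(res$model)
  expect_true("succ_out_of_range" %in% issue_codes(v))
  err <- v[[match("succ_out_of_range", issue_codes(v))]]
  expect_equal(err$severity, "error")
  expect_match(err$message, "the successor of state 10 is not defined")
  # on a circular list the same reaction is fine
  res <- build_text(c("[globals]", "k = 1", "[species]", "Cdh1(p{0:10}~circ) = 1",
                      "ClbM = 1", "[reactions]",
                      "r1 : Cdh1(p{0:10}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : k"))
  expect_length(validate(res$model), 0)
})

test_that("pred mirrors succ at the first state", {
  res <- build_text(c("[globals]", "k = 1", "[species]", "A(p{0:5}) = 1",
                      "[reactions]", "r1 : A(p{0:5}) -> A(pred(p)) | MA : k"))
  v <- validate(res$model)
  expect_true("pred_out_of_range" %in% issue_codes(v))
  expect_match(v[[1]]$message, "predecessor of state 0 is not defined")
})

test_that("undefined identifiers in expressions are incomplete-definition errors", {
  # two species whose expressions involve k1 and c, neither defined
  res <- build_text(c("[species]", "a = k1 * 2", "b = c + 1"))
  v <- validate(res$model)
  expect_length(error_issues(v), 2)
  msgs <- vapply(v, `[[`, "", "message")
  expect_true(any(grepl("'k1'", msgs)))
  expect_true(any(grepl("'c'", msgs)))
})

test_that("transfer compatibility requires the source values to be legal target states", {
  lines <- function(target_range) {
    c("[globals]", "k = 1",
      "[species]", "aatRNA_eEF1A_GTP = 1", "80S(codon{1:5}) = 1",
      sprintf("80S_aatRNA_eEF1A_GTP(codon{%s}) = 0", target_range),
      "[reactions]",
      "bind : aatRNA_eEF1A_GTP + 80S(codon) -> 80S_aatRNA_eEF1A_GTP(codon=80S.codon) | MA : k")
  }
  expect_length(validate(build_text(lines("1:5"))$model), 0)
  v <- validate(build_text(lines("1:3"))$model)
  expect_true("transfer_incompatible" %in% issue_codes(v))
})

test_that("function calls are checked for arity and parameter roles", {
  base <- c("[globals]", "N = 5", "k = 1",
            "[species]", "XP(i{0:N}) = 1", "Kin = 1",
            "[functions]", "dis(GLQ N, SITE i, GLQ k, SUB X, SUB K) = (N-i)*k*X*K",
            "[reactions]")
  ok <- build_text(c(base, "r : XP(i{0:N-1}) + Kin -> XP(succ(i)) + Kin | UD : dis(N, XP.i, k, XP, Kin)"))
  expect_length(validate(ok$model), 0)

  v <- validate(build_text(c(base, "r : XP(i{0:N-1}) + Kin -> XP(succ(i)) + Kin | UD : dis(N, XP.i, k, XP)"))$model)
  expect_true("bad_arity" %in% issue_codes(v))

  # SITE argument must be an accessor, not a bare name
  v <- validate(build_text(c(base, "r : XP(i{0:N-1}) + Kin -> XP(succ(i)) + Kin | UD : dis(N, k, k, XP, Kin)"))$model)
  expect_true("bad_role" %in% issue_codes(v))

  # SUB argument must name a participant
  v <- validate(build_text(c(base, "r : XP(i{0:N-1}) + Kin -> XP(succ(i)) + Kin | UD : dis(N, XP.i, k, XP, N)"))$model)
  expect_true("bad_role" %in% issue_codes(v))

  # undefined function
  v <- validate(build_text(c(base, "r : XP(i{0:N-1}) + Kin -> XP(succ(i)) + Kin | UD : nodef(N, XP.i, k, XP, Kin)"))$model)
  expect_true("undefined_function" %in% issue_codes(v))
})

test_that("a SITE argument over symbolic state labels is rejected", {
  v <- validate(build_text(c(
    "[globals]", "k = 1",
    "[species]", "S(s1{free,bound,hidden}) = 1",
    "[functions]", "f(SITE i, GLQ k) = i*k",
    "[reactions]", "r : S(s1{free,bound}) -> S(succ(s1)) | UD : f(S.s1, k)"))$model)
  expect_true("site_not_numeric" %in% issue_codes(v))
})

test_that("SUM restrictions are checked against the species state lists", {
  base <- c("[globals]", "low = 1", "middle = 5",
            "[species]", "Cdh1(p{0:10}) = 1")
  ok <- build_text(c(base, "[globals]"))  # no SUM yet
  # in-range symbolic restriction: no issue
  res <- build_text(c(base, "t := SUM(Cdh1;p{low:middle})"))
  expect_length(validate(res$model), 0)
  # fully outside the state list: error
  res <- build_text(c(base, "t := SUM(Cdh1;p{20:30})"))
  expect_true("sum_out_of_range" %in% issue_codes(validate(res$model)))
  # unknown site
  res <- build_text(c(base, "t := SUM(Cdh1;q{1:2})"))
  expect_true("undefined_site" %in% issue_codes(validate(res$model)))
})

test_that("operators in reactant patterns and ranges in products are rejected", {
  v <- validate(build_text(c("[globals]", "k = 1", "[species]", "A(p{0:3}) = 1",
                             "[reactions]", "r : A(succ(p)) -> A(p{0}) | MA : k"))$model)
  expect_true("bad_pattern" %in% issue_codes(v))
  v <- validate(build_text(c("[globals]", "k = 1", "[species]", "A(p{0:3}) = 1", "B(q{0:3}) = 1",
                             "[reactions]", "r : A(p{0:2}) -> B(q{0:2}) | MA : k"))$model)
  expect_true("bad_pattern" %in% issue_codes(v))
})

test_that("ranges over non-static variables are flagged where they parameterize states", {
  res <- build_text(c("[globals]", "h := 3 + 1", "[species]", "A(p{0:h}) = 1"))
  v <- validate(res$model)
  expect_true("range_not_static" %in% issue_codes(v))
})

test_that("validate is pure: two runs give identical issue lists", {
  res <- build_text(c("[species]", "a = k1 * 2", "b = c + 1",
                      "[reactions]", "r : a -> a + a"))
  m <- res$model
  expect_identical(validate(m), validate(m))
})

test_that("issues serialize as JSON lines with severity, code and location", {
  v <- validate(build_text(c("[species]", "a = k1 * 2"))$model)
  line <- issues_json(v)[[1]]
  parsed <- jsonlite::fromJSON(line)
  expect_equal(parsed$severity, "error")
  expect_equal(parsed$code, "undefined_ref")
  expect_true(is.numeric(parsed$line))
  expect_match(parsed$message, "k1")
})
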