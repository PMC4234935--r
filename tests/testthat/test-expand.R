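# Expansion of species, reactions, SUM aggregates and rate laws.

test_that("instance enumeration is the cartesian product in declaration order, last site fastest", {
  m <- build_text(c("[species]", "Cdh1(p{0:10}) = 1"))$model
  insts <- enumerate_instances(m$species[["Cdh1"]], m$globals)
  expect_length(insts, 11)
  expect_equal(insts[[1]]$name, "Cdh1_p0")
  expect_equal(insts[[11]]$name, "Cdh1_p10")

  m <- build_text(c("[species]", "X(a{0:1}, b{free,bound}) = 1"))$model
  insts <- enumerate_instances(m$species[["X"]], m$globals)
  expect_equal(vapply(insts, function(i) paste(i$states, collapse = ","), ""),
               c("0,free", "0,bound", "1,free", "1,bound"))

  m <- build_text(c("[species]", "ClbM = 1"))$model
  insts <- enumerate_instances(m$species[["ClbM"]], m$globals)
  expect_length(insts, 1)
  expect_equal(insts[[1]]$name, "ClbM")
})

test_that("the succ phosphorylation template expands to its ten single-state reactions", {
  m <- build_text(c("[globals]", "k = 1", "[species]", "Cdh1(p{0:10}) = 1",
                    "ClbM = 1", "[reactions]",
                    "r1 : Cdh1(p{0:9}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : k"))$model
  frs <- expand_reaction(m$reactions[["r1"]], m)
  expect_length(frs, 10)
  for (i in 1:10) {
    expect_equal(frs[[i]]$reactants, c(paste0("Cdh1_p", i - 1), "ClbM"))
    expect_equal(frs[[i]]$products, c(paste0("Cdh1_p", i), "ClbM"))
    expect_equal(frs[[i]]$kinetic_text,
                 sprintf("k * Cdh1_p%d * ClbM", i - 1))
  }
})

test_that("the translation-window reaction expands with transfer, modifiers and moving-window rules", {
  m <- translation_toy(length = 20, d = 2, window = 14)
  flat <- expand_model(m)
  expect_length(flat$reactions, 2)
  r1 <- flat$reactions[[1]]
  expect_equal(r1$reactants, "R_c1")
  expect_setequal(r1$products, c("P1_c2", "P2"))
  expect_equal(r1$modifiers, "M_c1")
  rule1 <- Filter(function(r) r$variable == "M_c1", flat$rules)[[1]]
  expect_equal(rule1$expr_text, paste(paste0("R_c", 2:15), collapse = " + "))
  rule2 <- Filter(function(r) r$variable == "M_c2", flat$rules)[[1]]
  expect_equal(rule2$expr_text, paste(paste0("R_c", 3:16), collapse = " + "))
})

test_that("transfer of state without an operator copies the matched state", {
  m <- build_text(c("[globals]", "k = 1",
                    "[species]", "aatRNA_eEF1A_GTP = 1", "80S(codon{1:3}) = 1",
                    "80S_aatRNA_eEF1A_GTP(codon{1:3}) = 0",
                    "[reactions]",
                    "bind : aatRNA_eEF1A_GTP + 80S(codon) -> 80S_aatRNA_eEF1A_GTP(codon=80S.codon) | MA : k"))$model
  frs <- expand_reaction(m$reactions[["bind"]], m)
  expect_length(frs, 3)
  for (i in 1:3) {
    expect_true(paste0("80S_codon", i) %in% frs[[i]]$reactants)
    expect_equal(frs[[i]]$products, paste0("80S_aatRNA_eEF1A_GTP_codon", i))
  }
})

test_that("a multistate catalyst with no pattern change carries its state through", {
  m <- build_text(c("[globals]", "k = 1",
                    "[species]", "A(p{0:1}) = 1", "E(q{0:2}) = 1",
                    "[reactions]", "r : A(p{0}) + E -> A(p{1}) + E | MA : k"))$model
  frs <- expand_reaction(m$reactions[["r"]], m)
  expect_length(frs, 3)   # E's unconstrained site iterates its full list
  expect_equal(frs[[1]]$reactants[2], "E_q0")
  expect_equal(frs[[1]]$products[2], "E_q0")
})

test_that("SUM aggregates ground to explicit sums of flat species", {
  m <- cdh1_toy()
  s <- expand_sum(parse_expression("SUM(Cdh1;p{1:10})"), m)
  expect_equal(expr_text(s), paste(paste0("Cdh1_p", 1:10), collapse = " + "))
  s <- expand_sum(parse_expression("SUM(Cdh1)"), m)
  expect_match(expr_text(s), "^Cdh1_p0 \\+ ")
  expect_length(gregexpr("Cdh1_p", expr_text(s))[[1]], 11)
  # moving window at M.c = 1 spans +1..+14
  mt <- translation_toy()
  s <- expand_sum(parse_expression("SUM(R;c{M.c+1:M.c+14})"), mt,
                  env = list("M.c" = 1))
  expect_equal(expr_text(s), paste(paste0("R_c", 2:15), collapse = " + "))
  # the window is truncated at the chain end, not an error
  s <- expand_sum(parse_expression("SUM(R;c{M.c+1:M.c+14})"), mt,
                  env = list("M.c" = 15))
  expect_equal(expr_text(s), paste(paste0("R_c", 16:20), collapse = " + "))
  # a selection with no admitted state is an error
  expect_error(expand_sum(parse_expression("SUM(Cdh1;p{20:30})"), m),
               "selects no state")
})

test_that("SUM weights multiply each term with the site value substituted", {
  m <- cdh1_toy()
  s <- expand_sum(parse_expression("SUM(Cdh1;p{1:3};Cdh1.p*2)"), m)
  expect_equal(expr_text(s),
               "1 * 2 * Cdh1_p1 + 2 * 2 * Cdh1_p2 + 3 * 2 * Cdh1_p3")
})

test_that("user-defined rate laws bind GLQ, SUB and SITE roles per instance", {
  m <- xp_phosphorylation(5, "disordered")
  frs <- expand_reaction(m$reactions[[1]], m)
  expect_length(frs, 5)
  expect_equal(frs[[4]]$kinetic_text, "(N - 3) * k * XP_i3 * Kin")
  # mass action over the same template only changes the formula
  mo <- xp_phosphorylation(5, "ordered")
  fro <- expand_reaction(mo$reactions[[1]], mo)
  expect_equal(lapply(fro, `[[`, "reactants"), lapply(frs, `[[`, "reactants"))
  expect_equal(fro[[4]]$kinetic_text, "k * XP_i3 * Kin")
})

test_that("binding a SITE argument to a symbolic state label fails", {
  m <- build_text(c(
    "[globals]", "k = 1",
    "[species]", "S(s1{free,bound,hidden}) = 1",
    "[functions]", "f(SITE i, GLQ k) = i*k",
    "[reactions]", "r : S(s1{free,bound}) -> S(succ(s1)) | UD : f(S.s1, k)"))$model
  expect_error(expand_reaction(m$reactions[[1]], m), "non-integer state")
})

test_that("expansion refuses a model with outstanding errors and lists them", {
  res <- build_text(c("[globals]", "k = 1", "[species]", "Cdh1(p{0:10}) = 1",
                      "ClbM = 1", "[reactions]",
                      "r1 : Cdh1(p{0:10}) + ClbM -> Cdh1(succ(p)) + ClbM | MA : k"))
  err <- tryCatch(expand_model(res$model), error = function(e) e)
  expect_s3_class(err, "msl_expand_refusal")
  expect_match(conditionMessage(err), "successor of state 10")
  expect_gte(length(err$issues), 1)
})

test_that("an empty admitted range expands to zero reactions with a warning, not an error", {
  res <- build_text(c("[globals]", "k = 1", "lo = 5", "hi = 2",
                      "[species]", "A(p{0:10}) = 1",
                      "[reactions]", "r : A(p{lo:hi}) -> A(p{0}) | MA : k"))
  v <- validate(res$model)
  expect_length(error_issues(v), 0)
  expect_true("empty_range" %in% issue_codes(v))
  flat <- expand_model(res$model)
  expect_length(flat$reactions, 0)
})

test_that("expansion output is deterministic across runs", {
  f1 <- expand_model(cdh1_toy())
  f2 <- expand_model(cdh1_toy())
  expect_identical(f1, f2)
  t1 <- tempfile(); t2 <- tempfile()
  write_sbml(f1, t1); write_sbml(f2, t2)
  expect_identical(readBin(t1, "raw", file.size(t1)),
                   readBin(t2, "raw", file.size(t2)))
})
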