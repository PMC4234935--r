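# Tokenizer and parser behaviour, canonical rendering, round trips.

test_that("species definitions parse: ranges, enumerations, zero sites, symbolic bounds", {
  sp <- parse_species("Cdh1(p{0:10})")
  expect_equal(sp$name, "Cdh1")
  expect_length(sp$sites, 1)
  expect_equal(sp$sites[[1]]$name, "p")
  expect_equal(sp$sites[[1]]$kind, "range")
  expect_equal(sp$sites[[1]]$lo$value, 0)
  expect_equal(sp$sites[[1]]$hi$value, 10)

  sp <- parse_species("Species(s1{free,bound,hidden})")
  expect_equal(sp$sites[[1]]$kind, "enumset")
  expect_equal(sp$sites[[1]]$labels, c("free", "bound", "hidden"))

  sp <- parse_species("ClbM")
  expect_length(sp$sites, 0)

  sp <- parse_species("Cdh1(p{low:high})")
  expect_equal(sp$sites[[1]]$lo$name, "low")
  expect_equal(sp$sites[[1]]$hi$name, "high")

  # whitespace inside patterns is insignificant
  expect_true(ast_identical(parse_species("Cdh1(p {0:10 })"),
                            parse_species("Cdh1(p{0:10})")))

  # circular marker
  sp <- parse_species("S(p{0:3}~circ)")
  expect_true(sp$sites[[1]]$circular)

  # names may start with a digit when not purely numeric
  sp <- parse_species("80S_aatRNA_eEF1A_GTP(codon{1:5})")
  expect_equal(sp$name, "80S_aatRNA_eEF1A_GTP")
})

test_that("malformed species definitions fail with located errors", {
  expect_s3_class(tryCatch(parse_species("Cdh1(p{})"), msl_parse_error = function(e) e),
                  "msl_parse_error")
  expect_s3_class(tryCatch(parse_species("Cdh1(p{0:10}"), msl_parse_error = function(e) e),
                  "msl_parse_error")
  err <- tryCatch(parse_species("Cdh1(p{0:1}, p{2:3})"),
                  msl_parse_error = function(e) e)
  expect_match(conditionMessage(err), "duplicate site")
  expect_false(is.na(err$line))
  expect_false(is.na(err$col))
  err <- tryCatch(parse_species("S(a{x,x})"), msl_parse_error = function(e) e)
  expect_match(conditionMessage(err), "duplicate state")
})

test_that("reactions parse: sides, stoichiometry by repetition, operators, modifiers", {
  r <- parse_reaction("Cdh1(p{0:9}) + ClbM -> Cdh1(succ(p)) + ClbM")
  expect_length(r$reactants, 2)
  expect_length(r$products, 2)
  pat <- r$products[[1]]$patterns[["p"]]
  expect_equal(pat$kind, "opcall")
  expect_equal(pat$op, "succ")

  r <- parse_reaction("R(c{1:d}) -> P1(c=succ(R.c)) + P2; M(c=R.c)")
  expect_length(r$modifiers, 1)
  m <- r$modifiers[[1]]$patterns[["c"]]
  expect_equal(m$kind, "transfer")
  expect_equal(m$src_species, "R")
  expect_equal(m$src_site, "c")
  expect_null(m$op)
  p1 <- r$products[[1]]$patterns[["c"]]
  expect_equal(p1$op, "succ")

  r <- parse_reaction("-> A")
  expect_length(r$reactants, 0)
  expect_length(r$products, 1)

  r <- parse_reaction("A + A -> B")
  expect_length(r$reactants, 2)

  expect_s3_class(tryCatch(parse_reaction("A + B"), msl_parse_error = function(e) e),
                  "msl_parse_error")
})

test_that("expressions parse: SUM forms, accessors, precedence", {
  e <- parse_expression("SUM(Cdh1;p{1:10})")
  expect_equal(e$kind, "sum")
  expect_equal(e$species, "Cdh1")
  expect_length(e$restr, 1)
  expect_equal(e$restr[[1]]$site, "p")
  expect_null(e$weight)

  e <- parse_expression("SUM(Cdh1)")
  expect_length(e$restr, 0)

  e <- parse_expression("SUM(R;c{M.c+1:M.c+14};2*R.c)")
  expect_length(e$restr, 1)
  expect_false(is.null(e$weight))

  e <- parse_expression("(N-i)*k*X*K")
  expect_equal(e$kind, "binop")
  expect_equal(e$op, "*")
  expect_equal(expr_text(e), "(N - i) * k * X * K")

  expect_equal(expr_text(parse_expression("a+b*c^2")), "a + b * c ^ 2")
  # structure is preserved through render/reparse, including right-nesting
  for (txt in c("a - (b - c)", "a / b / c", "2 ^ 3 ^ 2", "-(a + b)", "a * -b")) {
    expect_true(ast_identical(parse_expression(expr_text(parse_expression(txt))),
                              parse_expression(txt)),
                info = txt)
  }
})

test_that("model documents parse per entry and tolerate bad lines", {
  ast <- parse_model(readLines(test_msl("cdh1_toy.msl")))
  expect_length(ast$species, 2)
  expect_length(ast$reactions, 2)
  expect_length(ast$functions, 0)
  expect_length(ast$diagnostics, 0)

  expect_length(parse_model("")$species, 0)

  bad <- c("[species]", "A = 1", "[reactions]", "r1 : A -> -> B",
           "r2 : A -> A + A | MA : 1")
  ast <- parse_model(bad)
  expect_length(ast$diagnostics, 1)
  expect_length(ast$raw, 1)
  expect_length(ast$reactions, 1)   # the good line still parsed
  expect_equal(ast$diagnostics[[1]]$severity, "error")
  expect_equal(ast$diagnostics[[1]]$line, 4L)
})

test_that("parse -> unparse -> parse is a fixed point on every fixture", {
  for (f in c("cdh1_toy.msl", "xp_ordered.msl", "xp_disordered.msl",
              "translation_toy.msl", "nonconsecutive_demo.msl")) {
    a1 <- parse_model(readLines(test_msl(f)))
    a2 <- parse_model(unparse(a1))
    expect_true(ast_equal(a1, a2), info = f)
  }
  # enumerated state order is preserved verbatim, never sorted
  txt <- unparse(parse_model(c("[species]", "S(s2{2,4,6,8,0}) = 1")))
  expect_match(txt, "s2{2,4,6,8,0}", fixed = TRUE)
  # zero-site species prints without parentheses
  txt <- unparse(parse_model(c("[species]", "ClbM = 1")))
  expect_true("ClbM = 1" %in% strsplit(txt, "\n")[[1]])
})

test_that("AST nodes carry source locations", {
  ast <- parse_model(c("[species]", "A(p{0:2}) = 1", "[reactions]",
                       "r1 : A(p{0:1}) -> A(succ(p)) | MA : 1"))
  sp_pos <- attr(ast$species[[1]]$def, "pos")
  expect_equal(sp_pos[1], 2L)
  rx_pos <- attr(ast$reactions[[1]], "pos")
  expect_equal(rx_pos[1], 4L)
})
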