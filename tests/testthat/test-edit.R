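# Rename/delete refactoring and the save-with-errors contract.

test_that("renaming a species propagates to reactions, SUMs and ranges", {
  m <- cdh1_toy()
  m2 <- rename_entity(m, "Cdh1", "CDH1")
  txt <- unparse(m2)
  expect_false(grepl("\\bCdh1\\b", txt))   # zero occurrences of the old name
  expect_match(txt, "SUM(CDH1;p{1:maxP})", fixed = TRUE)
  expect_match(txt, "CDH1(succ(p))", fixed = TRUE)
  expect_length(validate(m2), 0)
})

test_that("rename then reverse-rename is the identity on the serialized model", {
  m <- cdh1_toy()
  back <- rename_entity(rename_entity(m, "Cdh1", "CDH1"), "CDH1", "Cdh1")
  expect_identical(unparse(back), unparse(m))
  g <- rename_entity(rename_entity(m, "maxP", "chainLen"), "chainLen", "maxP")
  expect_identical(unparse(g), unparse(m))
})

test_that("rename to the same name is the identity; collisions are errors leaving the model unchanged", {
  m <- cdh1_toy()
  expect_identical(unparse(rename_entity(m, "Cdh1", "Cdh1")), unparse(m))
  expect_error(rename_entity(m, "Cdh1", "ClbM"), "already in use")
  expect_error(rename_entity(m, "Cdh1", "9"), "not a legal identifier")
  expect_error(rename_entity(m, "nothing", "x"), "no entity")
})

test_that("renaming a site propagates to all reactions and aggregates", {
  m <- cdh1_toy()
  m2 <- rename_site(m, "Cdh1", "p", "ph")
  txt <- unparse(m2)
  expect_match(txt, "Cdh1(ph{0:maxP})", fixed = TRUE)
  expect_match(txt, "succ(ph)", fixed = TRUE)
  expect_match(txt, "SUM(Cdh1;ph{1:maxP})", fixed = TRUE)
  expect_length(validate(m2), 0)
  expect_error(rename_site(m, "Cdh1", "q", "x"), "no site")
})

test_that("renaming a component regenerates the auto-maintained complex name", {
  res <- build_text(c("[species]", "Net1(p{0:8}) = 1", "Cdc14 = 1",
                      "[complexes]", "Net1(p{0:5}) + Cdc14 | reactions"))
  m <- rename_entity(res$model, "Net1", "Net1P")
  expect_true("Net1P_Cdc14" %in% names(m$species))
  expect_true("Net1P_Cdc14_bind" %in% names(m$reactions))
  expect_false(any(grepl("\\bNet1_Cdc14\\b", unparse(m))))
  expect_length(validate(m), 0)
})

fig3_model <- function() {
  # species a; reaction consuming a; species d whose expression uses a;
  # global k1 whose expression uses a
  build_text(c("[globals]", "k1 = a + 1", "k = 1",
               "[species]", "a = 1", "b = 2", "d = a * 3",
               "[reactions]", "r1 : a -> b | MA : k"))$model
}

test_that("deleting a species offers cascade, numeric replacement, and leaving the inconsistency", {
  m <- fig3_model()
  # mixed per-class policies, as in an interactive walk-through:
  # delete the reaction, leave d's expression dangling, replace in k1
  res <- delete_entity(m, "a", policy = c(reactions = "cascade",
                                          expressions = "leave"))
  expect_false("r1" %in% names(res$model$reactions))
  expect_false("a" %in% names(res$model$species))
  expect_true(any(grepl("species 'd'", vapply(res$issues, `[[`, "", "message"))))
  v <- validate(res$model)
  expect_true("undefined_ref" %in% issue_codes(v))
  # ... and the inconsistent model still saves and re-loads losslessly
  reread <- parse_model(unparse(res$model))
  expect_true(ast_equal(reread, parse_model(unparse(
    build_model(reread, policy = "off")$model))))

  res2 <- delete_entity(m, "a", policy = c(reactions = "cascade",
                                           expressions = "replace"),
                        value = 5)
  expect_equal(expr_text(res2$model$globals[["k1"]]$expr), "5 + 1")
  expect_equal(expr_text(res2$model$species[["d"]]$default_initial), "5 * 3")
  expect_length(validate(res2$model), 0)

  res3 <- delete_entity(m, "a", policy = "cascade")
  expect_false("k1" %in% names(res3$model$globals))
  expect_false("d" %in% names(res3$model$species))
  v <- validate(res3$model)
  expect_false("undefined_ref" %in% issue_codes(v))  # no dangling references
})

test_that("a numeric value cannot replace a reaction participant", {
  m <- fig3_model()
  res <- delete_entity(m, "a", policy = "replace", value = 2)
  codes <- issue_codes(res$issues)
  expect_true("dangling_ref" %in% codes)
  expect_match(res$issues[[1]]$message, "cannot replace")
  # the expression references were still replaced
  expect_equal(expr_text(res$model$globals[["k1"]]$expr), "2 + 1")
})

test_that("deleting an unreferenced entity is clean", {
  m <- cdh1_toy()
  res <- delete_entity(m, "kd", policy = "leave")
  # kd is referenced by the dephos rate; delete something untouched instead
  m2 <- set_global_value(m, "kp", 1)
  res <- delete_entity(build_text(c("[globals]", "unused = 3",
                                    "[species]", "A = 1"))$model, "unused")
  expect_length(res$issues, 0)
  expect_length(validate(res$model), 0)
})

test_that("a model carrying parse errors saves and re-parses losslessly", {
  bad <- c("[species]", "A = 1", "[reactions]",
           "r1 : A -> -> B",            # malformed, kept verbatim
           "r2 : A -> A + A | MA : 1")
  ast <- parse_model(bad)
  expect_length(ast$diagnostics, 1)
  expect_true(ast_equal(ast, parse_model(unparse(ast))))
  # building and re-serializing preserves the raw entry too
  m <- build_model(ast, policy = "off")$model
  expect_match(unparse(m), "r1 : A -> -> B", fixed = TRUE)
})
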