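# Model construction: autocompletion policies, per-state initials,
# complexes, configuration.

test_that("autocompletion policy governs species referenced but never defined", {
  ast <- parse_model(c("[globals]", "k = 1", "[reactions]", "r1 : -> A | MA : k"))

  res <- build_model(ast, policy = "silent")
  expect_true("A" %in% names(res$model$species))
  expect_true("autocreated_species" %in% issue_codes(res$issues))
  expect_equal(issues_df(res$issues)$severity, "warning")
  expect_length(validate(res$model), 0)

  res <- build_model(ast, policy = "off")
  expect_false("A" %in% names(res$model$species))
  codes <- issue_codes(error_issues(res$issues))
  expect_true("undefined_species" %in% codes)

  res <- build_model(ast, policy = "confirm")
  expect_equal(res$pending, "A")
  expect_false("A" %in% names(res$model$species))
})

test_that("a fully defined model builds and validates with zero issues", {
  res <- read_msl(test_msl("cdh1_toy.msl"), policy = "off")
  expect_length(res$issues, 0)
  expect_length(validate(res$model), 0)
})

test_that("the default initial for auto-created species is configurable", {
  ast <- parse_model(c("[globals]", "k = 1", "[reactions]", "r1 : -> A | MA : k"))
  res <- build_model(ast, policy = "silent", config = list(default_initial = 7))
  expect_equal(res$model$species[["A"]]$default_initial$value, 7)
  cfg_file <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("autocompletion = off", "default_initial = 3  # amount",
               "default_delete = leave"), cfg_file)
  cfg <- read_config(cfg_file)
  expect_equal(cfg$autocompletion, "off")
  expect_equal(cfg$default_initial, 3)
  res <- build_model(ast, config = cfg)
  expect_false("A" %in% names(res$model$species))
  expect_error(read_config({
    f <- withr::local_tempfile(); writeLines("nonsense = 1", f); f
  }), "unknown config key")
})

test_that("per-state initial overrides attach; unlisted states inherit the default", {
  res <- build_text(c("[species]", "Cdh1(p{0:3}) = 2", "[initials]",
                      "Cdh1(p{0}) = 9", "Cdh1(p{2}) = 5"))
  expect_length(res$issues, 0)
  insts <- enumerate_instances(res$model$species[["Cdh1"]], res$model$globals)
  inits <- vapply(insts, `[[`, 1, "initial")
  expect_equal(inits, c(9, 2, 5, 2))
  # overriding an unknown state is an error issue, not a crash
  res <- build_text(c("[species]", "Cdh1(p{0:3}) = 2", "[initials]",
                      "Cdh1(p{7}) = 1"))
  expect_true("bad_initial" %in% issue_codes(validate(res$model)))
})

test_that("duplicate names are issues, and the first definition wins", {
  res <- build_text(c("[species]", "A = 1", "A(p{0:1}) = 2"))
  expect_true("duplicate_name" %in% issue_codes(res$issues))
  expect_length(res$model$species[["A"]]$sites, 0)
})

test_that("complexes: restricted tracked sites, auto-naming, generated reactions", {
  res <- build_text(c("[species]", "Net1(p{0:8}) = 1", "Cdc14 = 1",
                      "[complexes]", "Net1(p{0:5}) + Cdc14 | reactions"))
  expect_length(res$issues, 0)
  m <- res$model
  expect_true("Net1_Cdc14" %in% names(m$species))   # auto-name from components
  sl <- resolve_state_list(m$species[["Net1_Cdc14"]]$sites[[1]], m$globals)
  expect_equal(sl$labels, as.character(0:5))
  expect_setequal(c("Net1_Cdc14_bind", "Net1_Cdc14_unbind"),
                  names(m$reactions))
  expect_length(validate(m), 0)
  flat <- expand_model(m)
  # 9 Net1 + Cdc14 + 6 complex forms; 6 bind + 6 unbind reactions
  expect_length(flat$species, 16)
  expect_length(flat$reactions, 12)
  # transfer of state: complex keeps the component state it was built from
  bind3 <- Filter(function(r) "Net1_p3" %in% r$reactants, flat$reactions)[[1]]
  expect_true("Net1_Cdc14_p3" %in% bind3$products)
})

test_that("a complex of two zero-site species is a plain species with two mass-action reactions", {
  res <- build_text(c("[species]", "A = 1", "B = 1",
                      "[complexes]", "AB : A + B | reactions"))
  expect_length(res$issues, 0)
  flat <- expand_model(res$model)
  expect_setequal(vapply(flat$species, `[[`, "", "name"), c("A", "B", "AB"))
  expect_length(flat$reactions, 2)
  kin <- vapply(flat$reactions, `[[`, "", "kinetic_text")
  expect_true(any(grepl("AB_kon \\* A \\* B", kin)))
})

test_that("restrictions outside the component's state list are errors", {
  res <- build_text(c("[species]", "Net1(p{0:4}) = 1", "Cdc14 = 1",
                      "[complexes]", "Net1(p{0:7}) + Cdc14"))
  expect_true("restriction_invalid" %in% issue_codes(validate(res$model)))
})

test_that("build_complex mirrors the declaration form", {
  m <- build_text(c("[species]", "Net1(p{0:8}) = 1", "Cdc14 = 1"))$model
  out <- build_complex(m, c("Net1(p{0:5})", "Cdc14"), generate_reactions = TRUE)
  expect_length(out$issues, 0)
  expect_equal(out$complex$name, "Net1_Cdc14")
  expect_true("Net1_Cdc14_bind" %in% names(out$model$reactions))
})
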