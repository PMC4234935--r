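# The fixture builders: clean validation, closed-form counts, and
# single-variable rescaling.

test_that("every fixture validates cleanly and matches its golden file", {
  builders <- list(cdh1_toy.msl = cdh1_toy,
                   xp_ordered.msl = function() xp_phosphorylation(5, "ordered"),
                   xp_disordered.msl = function() xp_phosphorylation(5, "disordered"),
                   translation_toy.msl = translation_toy,
                   nonconsecutive_demo.msl = nonconsecutive_demo)
  for (f in names(builders)) {
    m <- builders[[f]]()
    expect_equal(length(validate(m)), 0L, info = f)
    expect_identical(unparse(m), paste(readLines(test_msl(f)), collapse = "\n"),
                     info = f)
  }
})

test_that("the phosphorylation chain obeys the 2*maxP count law across chain lengths", {
  for (maxP in c(1, 3, 7, 12)) {
    flat <- expand_model(cdh1_toy(maxP))
    expect_length(flat$reactions, 2 * maxP)
    expect_length(flat$species, maxP + 2)  # maxP+1 chain states + catalyst
  }
  # the aggregate grounds to maxP terms
  flat <- expand_model(cdh1_toy(10))
  rule <- Filter(function(r) r$variable == "Cdh1T", flat$rules)[[1]]
  expect_length(strsplit(rule$expr_text, " + ", fixed = TRUE)[[1]], 10)
})

test_that("the distributive phosphorylation fixture expands to N reactions for both mechanisms", {
  for (N in c(1, 4, 10)) {
    fo <- expand_model(xp_phosphorylation(N, "ordered"))
    fd <- expand_model(xp_phosphorylation(N, "disordered"))
    expect_length(fo$reactions, N)
    expect_length(fd$reactions, N)
    # identical reaction graphs, different kinetic formulas
    expect_equal(lapply(fo$reactions, `[[`, "reactants"),
                 lapply(fd$reactions, `[[`, "reactants"))
    expect_equal(lapply(fo$reactions, `[[`, "products"),
                 lapply(fd$reactions, `[[`, "products"))
    expect_false(identical(vapply(fo$reactions, `[[`, "", "kinetic_text"),
                           vapply(fd$reactions, `[[`, "", "kinetic_text")))
  }
  # disordered coefficient at the last step is (N-(N-1))*k = k
  fd <- expand_model(xp_phosphorylation(5, "disordered"))
  expect_equal(fd$reactions[[5]]$kinetic_text, "(N - 4) * k * XP_i4 * Kin")
})

test_that("the translation toy reproduces the listed expansion pair at d = 2", {
  flat <- expand_model(translation_toy(length = 20, d = 2))
  expect_length(flat$reactions, 2)
  expect_equal(flat$reactions[[1]]$reactants, "R_c1")
  expect_setequal(flat$reactions[[1]]$products, c("P1_c2", "P2"))
  expect_equal(flat$reactions[[1]]$modifiers, "M_c1")
  expect_equal(flat$reactions[[2]]$modifiers, "M_c2")
})

test_that("scaling the mRNA chain or the window is a single-variable change", {
  count_species <- function(len, d) 2 * len + 1 + d   # R + P1 chains, P2, M instances
  m20 <- translation_toy(length = 20, d = 3)
  f20 <- expand_model(m20)
  expect_length(f20$species, count_species(20, 3))
  m300 <- set_global_value(m20, "len", 300)
  f300 <- expand_model(m300)
  expect_length(f300$species, count_species(300, 3))
  expect_length(f300$reactions, 3)
})

test_that("the nonconsecutive-state demo steps symbolic and skipping-integer sites together", {
  m <- nonconsecutive_demo()
  insts <- enumerate_instances(m$species[["S"]], m$globals)
  expect_length(insts, 15)   # 3 x 5 cartesian product
  flat <- expand_model(m)
  expect_length(flat$reactions, 1)
  expect_equal(flat$reactions[[1]]$reactants, "S_s1free_s22")
  expect_equal(flat$reactions[[1]]$products, "S_s1bound_s24")
})
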