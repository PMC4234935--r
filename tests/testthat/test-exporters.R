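# SBML and CSV export, model statistics, command-line interface.

test_that("SBML export of the phosphorylation chain has the expected shape and passes the checker", {
  flat <- expand_model(cdh1_toy())
  doc <- write_sbml(flat)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  expect_length(xml2::xml_find_all(doc, "//s:reaction", ns), 20)
  expect_length(xml2::xml_find_all(doc, "//s:species", ns), 12)
  expect_length(xml2::xml_find_all(doc, "//s:assignmentRule", ns), 1)
  expect_identical(sbml_check(doc), character(0))
})

test_that("every fixture exports SBML that passes consistency checking", {
  fixtures <- list(cdh1 = cdh1_toy(), xp_o = xp_phosphorylation(5, "ordered"),
                   xp_d = xp_phosphorylation(5, "disordered"),
                   transl = translation_toy(), nonconsec = nonconsecutive_demo())
  for (nm in names(fixtures)) {
    doc <- write_sbml(expand_model(fixtures[[nm]]))
    expect_identical(sbml_check(doc), character(0), info = nm)
  }
})

test_that("illegal SBML ids are sanitized with the original kept as the display name", {
  m <- build_text(c("[globals]", "k = 1", "[species]", "80S = 1", "A = 1",
                    "[reactions]", "r : 80S -> A | MA : k"))$model
  doc <- write_sbml(expand_model(m))
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  sp <- xml2::xml_find_all(doc, "//s:species", ns)
  ids <- xml2::xml_attr(sp, "id")
  nms <- xml2::xml_attr(sp, "name")
  expect_true("_80S" %in% ids)
  expect_true("80S" %in% nms)
  expect_identical(sbml_check(doc), character(0))
})

test_that("an empty model gives a minimal valid SBML document", {
  flat <- expand_model(build_text(character())$model)
  doc <- write_sbml(flat)
  expect_identical(sbml_check(doc), character(0))
})

test_that("the structural checker actually detects broken documents", {
  flat <- expand_model(cdh1_toy())
  doc <- write_sbml(flat)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "s")
  node <- xml2::xml_find_first(doc, "//s:speciesReference", ns)
  xml2::xml_set_attr(node, "species", "no_such_species")
  errs <- sbml_check(doc)
  expect_true(any(grepl("no_such_species", errs)))
})

test_that("CSV tables have deterministic shape and round-trip", {
  flat <- expand_model(cdh1_toy())
  dir <- withr::local_tempdir()
  write_tables(flat, dir)
  tabs <- read_tables(dir)
  expect_equal(nrow(tabs$reactions), 20)
  expect_equal(names(tabs$reactions), c("name", "reaction", "kinetic_law"))
  expect_equal(tabs$species, flat_species_table(flat))
  expect_equal(tabs$reactions, flat_reaction_table(flat))
  expect_equal(tabs$parameters, flat_parameter_table(flat))
  expect_match(tabs$reactions$reaction[1], "Cdh1_p0 \\+ ClbM -> Cdh1_p1 \\+ ClbM")

  # header-only files for the empty model
  empty <- expand_model(build_text(character())$model)
  dir2 <- withr::local_tempdir()
  write_tables(empty, dir2)
  expect_equal(nrow(read_tables(dir2)$species), 0)
})

test_that("model statistics report counts and reduction fractions", {
  m <- cdh1_toy()
  s <- model_stats(m)
  expect_equal(s$reactions_compact, 2)
  expect_equal(s$reactions_flat, 20)
  expect_equal(s$reaction_reduction, 0.9)
  expect_equal(s$species_flat, 12)

  # a model with no multistate species reduces by nothing
  m0 <- build_text(c("[globals]", "k = 1", "[species]", "A = 1", "B = 1",
                     "[reactions]", "r : A -> B | MA : k"))$model
  s0 <- model_stats(m0)
  expect_equal(s0$reaction_reduction, 0)
  expect_equal(s0$species_reduction, 0)

  sx <- model_stats(xp_phosphorylation(5))
  expect_equal(sx$reactions_compact, 1)
  expect_equal(sx$reactions_flat, 5)
})

test_that("the command-line interface validates, expands, exports and reports stats", {
  dir <- withr::local_tempdir()
  model_file <- file.path(dir, "cdh1.msl")
  writeLines(unparse(cdh1_toy()), model_file)
  sink_file <- file.path(dir, "out.txt")

  con <- file(sink_file, "w")
  code <- msl_cli(c("stats", model_file), out_stream = con)
  close(con)
  expect_equal(code, 0L)
  stats <- jsonlite::fromJSON(readLines(sink_file))
  expect_equal(stats$reactions_flat, 20)
  expect_equal(stats$reaction_reduction, 0.9)

  con <- file(sink_file, "w")
  code <- msl_cli(c("export", model_file, "--format", "sbml",
                    "--out", file.path(dir, "m.xml")), out_stream = con)
  close(con)
  expect_equal(code, 0L)
  expect_identical(sbml_check(file.path(dir, "m.xml")), character(0))

  con <- file(sink_file, "w")
  code <- msl_cli(c("expand", model_file, "--out", file.path(dir, "flat.msl")),
                  out_stream = con)
  close(con)
  expect_equal(code, 0L)
  reflat <- read_msl(file.path(dir, "flat.msl"), policy = "off")
  expect_length(reflat$issues, 0)
  expect_length(reflat$model$reactions, 20)

  # a model with undefined references exits nonzero with JSON diagnostics
  bad_file <- file.path(dir, "bad.msl")
  writeLines(c("[species]", "a = k1 * 2", "b = c + 1"), bad_file)
  con <- file(sink_file, "w")
  code <- msl_cli(c("validate", bad_file), out_stream = con)
  close(con)
  expect_equal(code, 1L)
  diags <- lapply(readLines(sink_file), jsonlite::fromJSON)
  expect_gte(length(diags), 2)
  expect_true(all(vapply(diags, function(d) d$severity, "") == "error"))

  con <- file(nullfile(), "w")
  expect_equal(msl_cli(c("validate", file.path(dir, "missing.msl")),
                       out_stream = con), 2L)
  expect_equal(msl_cli(character(0), out_stream = con), 2L)
  close(con)
})

test_that("export output is byte-identical across runs", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "a.xml"); f2 <- file.path(dir, "b.xml")
  write_sbml(expand_model(translation_toy()), f1)
  write_sbml(expand_model(translation_toy()), f2)
  expect_identical(readLines(f1), readLines(f2))
  d1 <- file.path(dir, "t1"); d2 <- file.path(dir, "t2")
  write_tables(expand_model(translation_toy()), d1)
  write_tables(expand_model(translation_toy()), d2)
  expect_identical(readLines(file.path(d1, "reactions.csv")),
                   readLines(file.path(d2, "reactions.csv")))
})
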