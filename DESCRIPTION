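Package: flatreact
Title: Compile Compact Multistate Biochemical Models into Flat Reaction
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A text-based language and compiler for compact multistate
    biochemical models. Species carry named sites with ordered
    (optionally circular) state lists; reactions are templates over
    state ranges using successor/predecessor operators, transfer of
    state, and SUM aggregates. Models are validated with severity-graded
    diagnostics (a model with errors remains representable and
    saveable), refactored with user-selectable rename/delete policies,
    and expanded into the equivalent single-state reaction network for
    export to SBML Level 3 Version 1 or flat CSV tables.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
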