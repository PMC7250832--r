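Package: gemflux
Title: Constraint-Based Analysis of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and interrogating genome-scale metabolic
    models of bacteria: flux balance analysis (FBA) with a built-in
    bounded-variable simplex solver, parsimonious flux distributions,
    carbon/nitrogen source screening, single-gene deletion (essentiality)
    screens, dynamic FBA of batch cultures including anaerobic nitrate
    respiration, GIMME-style integration of RNA-seq (FPKM) expression data
    into condition-specific models, artificially-centered hit-and-run flux
    sampling, and reconstruction utilities (reciprocal-best-hit ortholog
    filtering, draft model projection and merging, genome-derived biomass
    coefficients, uptake-rate estimation from batch time courses). Models
    are read and written as plain tab-separated reaction/metabolite sheets
    or SBML Level 3 with the fbc extension. A synthetic toy network with a
    TCA cycle, glyoxylate shunt, beta-oxidation-like substrate funnels and
    a nitrate-respiration branch supports fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    xml2,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    boot
Config/testthat/edition: 3
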