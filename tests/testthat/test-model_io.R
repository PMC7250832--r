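# Round-trip identity through the TSV sheets and SBML, plus the auxiliary
# readers (media, expression tables, hit tables).

models_equal <- function(a, b) {
  expect_identical(a$reactions$id, b$reactions$id)
  expect_identical(sort(a$metabolites$id), sort(b$metabolites$id))
  expect_equal(a$reactions$lb, b$reactions$lb, tolerance = 1e-12)
  expect_equal(a$reactions$ub, b$reactions$ub, tolerance = 1e-12)
  expect_identical(vapply(a$reactions$gpr, gpr_string, character(1),
                          USE.NAMES = FALSE),
                   vapply(b$reactions$gpr, gpr_string, character(1),
                          USE.NAMES = FALSE))
  for (rid in a$reactions$id) {
    sa <- a$stoichiometry[[rid]]; sb <- b$stoichiometry[[rid]]
    expect_equal(sa[sort(names(sa))], sb[sort(names(sb))], tolerance = 1e-12,
                 info = rid)
  }
  expect_identical(sort(a$genes), sort(b$genes))
  expect_identical(a$objectives[sort(names(a$objectives))],
                   b$objectives[sort(names(b$objectives))])
}

test_that("model sheets round-trip the toy model exactly", {
  m <- make_toy_model()
  rs <- tempfile(fileext = ".tsv"); ms <- tempfile(fileext = ".tsv")
  write_model_tables(m, rs, ms)
  m2 <- read_model_tables(rs, ms, quiet = TRUE)
  models_equal(m, m2)
  # second generation is byte-identical (deterministic serialization)
  rs2 <- tempfile(fileext = ".tsv"); ms2 <- tempfile(fileext = ".tsv")
  write_model_tables(m2, rs2, ms2)
  expect_identical(readLines(rs), readLines(rs2))
  expect_identical(readLines(ms), readLines(ms2))
})

test_that("sheet round trip holds across toy model variants", {
  for (variant in list(
    make_toy_model(include_phb_branch = FALSE),
    make_toy_model(include_nitrate_respiration = FALSE),
    make_toy_model(include_glyoxylate_shunt = FALSE),
    make_toy_model(n_isozyme_pairs = 2))) {
    rs <- tempfile(fileext = ".tsv"); ms <- tempfile(fileext = ".tsv")
    write_model_tables(variant, rs, ms)
    models_equal(variant, read_model_tables(rs, ms, quiet = TRUE))
  }
})

test_that("SBML L3+fbc round-trips the toy model", {
  m <- make_toy_model()
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f, quiet = TRUE)
  models_equal(m, m2)
  expect_identical(m2$reactions$kind, m$reactions$kind)
  expect_equal(m2$ngam_aerobic, m$ngam_aerobic)
  expect_equal(m2$ngam_anaerobic, m$ngam_anaerobic)
  # formulas and charges survive
  expect_identical(m2$metabolites$formula[match(m$metabolites$id,
                                                m2$metabolites$id)],
                   m$metabolites$formula)
})

test_that("FBA gives the same optimum on the model read back from SBML", {
  m <- make_toy_model()
  f <- tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f, quiet = TRUE)
  med <- toy_minimal_medium("EX_ttl_e", -10)
  expect_equal(solve_fba(m2, med)$objective_value,
               solve_fba(m, med)$objective_value, tolerance = 1e-9)
})

test_that("sheet parsing errors carry the offending row", {
  rs <- tempfile(fileext = ".tsv"); ms <- tempfile(fileext = ".tsv")
  m <- make_toy_model()
  write_model_tables(m, rs, ms)
  bad <- readLines(rs)
  bad[3] <- sub("\t[^\t]*->", "\tnonsense", bad[3])  # break a formula
  writeLines(bad, rs)
  expect_error(read_model_tables(rs, ms, quiet = TRUE), "row 2")
  # empty sheet
  writeLines(readLines(rs)[1], rs)
  expect_error(read_model_tables(rs, ms, quiet = TRUE), "no reactions")
})

test_that("reaction formula defaults: '->' irreversible, '<=>' reversible", {
  rs <- tempfile(fileext = ".tsv"); ms <- tempfile(fileext = ".tsv")
  writeLines(c("id\tname\tformula\tgpr\tsubsystem\tlower_bound\tupper_bound\tconfidence",
               "BIOMASS_x\tb\ta[c] ->\t\t\t\t\t",
               "R1\tr\ta[c] <=> b[c]\t\t\t\t\t",
               "R2\tr\tb[c] -> a[c]\t\t\t\t\t"), rs)
  writeLines(c("id\tname\tcompartment\tformula\tcharge",
               "a[c]\ta\tc\t\t", "b[c]\tb\tc\t\t"), ms)
  m <- read_model_tables(rs, ms, quiet = TRUE)
  expect_equal(m$reactions$lb, c(0, -1000, 0))
  expect_equal(m$reactions$ub, c(1000, 1000, 1000))
})

test_that("medium configs round-trip through YAML and JSON", {
  med <- toy_minimal_medium("EX_dcn_e", -7.5, aerobic = FALSE)
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_medium(med, f)
    m2 <- read_medium(f)
    expect_equal(m2$bounds[sort(names(m2$bounds))],
                 med$bounds[sort(names(med$bounds))])
    expect_identical(m2$aerobic, med$aerobic)
  }
})

test_that("expression tables round-trip and reject bad input", {
  p <- expression_profile("c1", c(gA = 12.5, gB = 0, gC = 3.75))
  f <- tempfile(fileext = ".tsv")
  write_expression(p, f)
  p2 <- read_expression(f, "c1")
  expect_equal(p2$fpkm, p$fpkm)
  expect_error(expression_profile("bad", c(gA = -1)))
})

test_that("hit-table reader enforces the outfmt-6-like columns", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("qseqid\tsseqid\tpident\tqcovs\tscovs\tevalue",
               "q1\ts1\t45\t85\t90\t1e-30"), f)
  h <- read_hits(f)
  expect_equal(nrow(h), 1)
  writeLines(c("qseqid\tsseqid", "q1\ts1"), f)
  expect_error(read_hits(f), "lacks columns")
})
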