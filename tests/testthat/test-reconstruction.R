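# Ortholog filtering, draft projection/merging, biomass coefficients and
# uptake-rate estimation.

hit_row <- function(q, s, id, qc, sc, ev)
  data.frame(qseqid = q, sseqid = s, pident = id, qcovs = qc, scovs = sc,
             evalue = ev, stringsAsFactors = FALSE)

test_that("reciprocal best hits require mutual best and all thresholds", {
  fwd <- rbind(hit_row("q1", "s1", 45, 85, 90, 1e-30),
               hit_row("q2", "s2", 39, 90, 90, 1e-40),   # identity fails
               hit_row("q3", "s3", 60, 95, 95, 1e-50),
               hit_row("q4", "s4", 50, 85, 85, 1e-25))
  rev <- rbind(hit_row("s1", "q1", 45, 90, 85, 1e-30),
               hit_row("s2", "q2", 60, 90, 90, 1e-40),
               hit_row("s3", "qX", 60, 95, 95, 1e-60),   # not mutual best
               hit_row("s3", "q3", 60, 95, 95, 1e-50),
               hit_row("s4", "q4", 50, 85, 85, 1e-25))
  pairs <- filter_rbh(fwd, rev)
  expect_identical(pairs$query, c("q1", "q4"))
  # e-value threshold is strict
  fwd2 <- hit_row("q1", "s1", 45, 85, 90, 1e-20)
  rev2 <- hit_row("s1", "q1", 45, 85, 90, 1e-30)
  expect_equal(nrow(filter_rbh(fwd2, rev2)), 0)
  # idempotent and order-invariant
  expect_identical(filter_rbh(fwd[4:1, ], rev[5:1, ]), pairs)
})

test_that("GPR curation thresholds are strict and cover both proteins", {
  hits <- rbind(hit_row("a", "x", 35, 75, 80, 1e-10),
                hit_row("b", "y", 35, 75, 60, 1e-10),   # subject coverage
                hit_row("c", "z", 30, 75, 80, 1e-10),   # boundary identity
                hit_row("d", "w", 35, 75, 80, 1e-5))    # boundary e-value
  acc <- gpr_curation_filter(hits)
  expect_identical(acc$qseqid, "a")
})

test_that("projection keeps satisfiable GPRs and merging unions donors", {
  dA <- tiny_donor(c("R1", "R2", "R3", "R4", "R5"),
                   c("gA1", "gA2 and gA3", "gA4 or gA5", "", "gA6"))
  dB <- tiny_donor(c("R1", "R2", "R6", "R7"),
                   c("gB1", "gB2", "gB3", "gB4"))
  mapA <- c(gA1 = "t1", gA2 = "t2", gA3 = "t3", gA4 = "t4", gA6 = "t6",
            gA5 = NA)
  mapA <- mapA[!is.na(mapA)]
  mapB <- c(gB1 = "t1b", gB2 = "t2b", gB3 = "t3b", gB4 = "t4b")
  draft <- project_and_merge(list(dA, dB), list(mapA, mapB),
                             donor_names = c("donor-A", "donor-B"))
  # 5 + 4 reactions with 2 shared ids -> 7
  expect_equal(nrow(draft$reactions), 7)
  expect_identical(unname(draft$provenance[c("R1", "R2")]), c("both", "both"))
  expect_identical(unname(draft$provenance["R6"]), "donor-B")
  # OR survives the loss of one isozyme; orphan reactions carried as-is
  expect_identical(draft$reactions$gpr[draft$reactions$id == "R3"], "t4")
  expect_identical(draft$reactions$gpr[draft$reactions$id == "R4"], "")
  # merged GPRs are OR-ed across donors
  expect_identical(draft$reactions$gpr[draft$reactions$id == "R1"],
                   "t1 or t1b")
})

test_that("a reaction whose only gene lacks an ortholog is excluded", {
  dA <- tiny_donor(c("R1", "R2"), c("gA1", "gA9"))
  draft <- project_and_merge(list(dA), list(c(gA1 = "t1")))
  expect_identical(draft$reactions$id, "R1")
  # AND with a missing mandatory subunit fails too
  dB <- tiny_donor(c("R1", "R2"), c("gA1", "gA1 and gA9"))
  draft2 <- project_and_merge(list(dB), list(c(gA1 = "t1")))
  expect_identical(draft2$reactions$id, "R1")
})

test_that("conflicting stoichiometry across donors is an error", {
  dA <- tiny_donor("R1", "gA1")
  dB <- tiny_donor("R1", "gB1")
  dB$stoichiometry$R1 <- c("x[c]" = -2, "m_R1[c]" = 1)
  expect_error(project_and_merge(list(dA, dB),
                                 list(c(gA1 = "t1"), c(gB1 = "t2"))),
               "conflicting stoichiometry")
})

test_that("projection output is donor-order invariant up to provenance", {
  dA <- tiny_donor(c("R1", "R2", "R3"), c("gA1", "gA2", ""))
  dB <- tiny_donor(c("R2", "R4"), c("gB1", "gB2"))
  maps <- list(c(gA1 = "t1", gA2 = "t2"), c(gB1 = "t3", gB2 = "t4"))
  ab <- project_and_merge(list(dA, dB), maps)
  ba <- project_and_merge(list(dB, dA), rev(maps))
  expect_identical(sort(ab$reactions$id), sort(ba$reactions$id))
})

test_that("poly-alanine proteome puts the whole protein fraction on alanine", {
  pf <- write_tmp_fasta(list(p1 = strrep("A", 60)), tempfile(fileext = ".faa"))
  gf <- write_tmp_fasta(list(c1 = strrep("ACGT", 30)), tempfile(fileext = ".fna"))
  bc <- biomass_coefficients(pf, gf)
  expect_gt(bc$amino_acids[["A"]], 0)
  expect_equal(sum(bc$amino_acids[names(bc$amino_acids) != "A"]), 0)
  # 1000 * 0.55 / 71.0788 mmol Ala per gDW
  expect_equal(bc$amino_acids[["A"]], 1000 * 0.55 / 71.0788,
               tolerance = 1e-9)
})

test_that("two-protein proteome coefficients match hand arithmetic", {
  # p1 = AG, p2 = GGV  ->  counts A:1, G:3, V:1
  pf <- write_tmp_fasta(list(p1 = "AG", p2 = "GGV"),
                        tempfile(fileext = ".faa"))
  gf <- write_tmp_fasta(list(c1 = "ATGC"), tempfile(fileext = ".fna"))
  bc <- biomass_coefficients(pf, gf)
  denom <- 1 * 71.0788 + 3 * 57.0519 + 1 * 99.1326
  expect_equal(bc$amino_acids[["A"]], 1000 * 0.55 * 1 / denom, tolerance = 1e-9)
  expect_equal(bc$amino_acids[["G"]], 1000 * 0.55 * 3 / denom, tolerance = 1e-9)
  expect_equal(bc$amino_acids[["V"]], 1000 * 0.55 * 1 / denom, tolerance = 1e-9)
})

test_that("a 50% GC genome gives equal dNTP coefficients and closure holds", {
  pf <- write_tmp_fasta(list(p1 = "MKLV"), tempfile(fileext = ".faa"))
  gf <- write_tmp_fasta(list(c1 = strrep("ATGC", 25)),
                        tempfile(fileext = ".fna"))
  bc <- biomass_coefficients(pf, gf)
  # A+T counted with T+A (both strands), G+C with C+G: all four equal here
  expect_equal(length(unique(round(bc$dntps, 12))), 1)
  closure <- biomass_mass_closure(bc)
  expect_lt(abs(closure[["total"]] - 1000) / 1000, 0.01)
  # per class, mass equals the class fraction within 1%
  expect_equal(closure[["protein"]], 550, tolerance = 0.01)
  expect_equal(closure[["rna"]], 205, tolerance = 0.01)
  expect_equal(closure[["dna"]], 31, tolerance = 0.01)
  expect_error(biomass_coefficients(pf, gf,
                                    mass_fractions = c(protein = 0.4)),
               "sum to 1")
})

test_that("biomass reaction row is sheet-compatible", {
  pf <- write_tmp_fasta(list(p1 = "MKLV"), tempfile(fileext = ".faa"))
  gf <- write_tmp_fasta(list(c1 = "ATGCATGC"), tempfile(fileext = ".fna"))
  row <- biomass_reaction_row(biomass_coefficients(pf, gf))
  parsed <- parse_reaction_formula(row$formula)
  expect_true("atp[c]" %in% names(parsed$stoich))
  expect_equal(parsed$stoich[["adp[c]"]], 40)  # GAM appears as product too
})

test_that("uptake-rate regression recovers configured rates", {
  # a slow batch (mu ~ 0.2/h), so the trapezoidal biomass integral is tight
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_hb3_e", -0.33)
  cfg <- dfba_config(initial_biomass = 0.05,
                     initial_concentrations = c(EX_hb3_e = 30),
                     uptake_bounds = list(EX_hb3_e = -0.33),
                     timestep = 0.25, n_steps = 80, medium = med)
  tc <- make_batch_timecourse(m, cfg, noise_sd = 0, seed = 1)
  # use the window before depletion (uptake bound still binding)
  keep <- which(tc$concentration$conc > 1)
  est <- suppressWarnings(estimate_uptake_rate(      # lm flags the exact fit
    lapply(tc$concentration, `[`, keep), lapply(tc$biomass, `[`, keep)))
  expect_lt(abs(est$rate - (-0.33)) / 0.33, 0.001)
  # noisy replicates: recovery within 3 SE, SE honest
  set.seed(99)
  errs <- ses <- numeric(20)
  for (i in 1:20) {
    tcn <- make_batch_timecourse(m, cfg, noise_sd = 0.02 * 30, seed = 100 + i)
    estn <- estimate_uptake_rate(
      lapply(tcn$concentration, `[`, keep), lapply(tcn$biomass, `[`, keep))
    errs[i] <- estn$rate - (-0.33); ses[i] <- estn$se
  }
  expect_gt(mean(abs(errs) <= 3 * ses), 0.85)
  expect_lt(abs(mean(errs)), 3 * mean(ses))
  # degenerate inputs
  expect_error(estimate_uptake_rate(list(time = c(0, 1), conc = c(5, 4)),
                                    list(time = c(0, 1), biomass = c(1, 1))),
               "3 time points")
  flat <- suppressWarnings(estimate_uptake_rate(
    list(time = 0:5, conc = rep(8, 6)),
    list(time = 0:5, biomass = exp(0.2 * (0:5)))))
  expect_equal(flat$rate, 0, tolerance = 1e-12)
})

test_that("biomass precursor check reports the gap when a route is removed", {
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_hb3_e", -10)
  rep0 <- check_biomass_precursors(m, med)
  expect_true(all(rep0$producible))
  # closing both gluconeogenic routes leaves gcp unproducible
  m2 <- m
  off <- m2$reactions$id %in% c("ICL", "GCS")
  m2$reactions$lb[off] <- 0; m2$reactions$ub[off] <- 0
  rep1 <- check_biomass_precursors(m2, med)
  expect_false(rep1$producible[rep1$metabolite == "gcp[c]"])
  expect_true(rep1$producible[rep1$metabolite == "ac[c]"])
})
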