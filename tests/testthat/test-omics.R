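# Expression integration: thresholds, reaction expression, GIMME models,
# flux sampling and ratio maps.

test_that("FPKM threshold uses linear interpolation between order statistics", {
  p <- expression_profile("t", c(g1 = 1, g2 = 2, g3 = 3, g4 = 4))
  expect_equal(fpkm_threshold(p), 1.75)
  expect_equal(fpkm_threshold(expression_profile("t", c(a = 7, b = 7, c = 7, d = 7))), 7)
  expect_error(fpkm_threshold(expression_profile("t", numeric(0))))
  # thresholds are monotone in the quantile
  set.seed(3)
  p2 <- expression_profile("t", stats::setNames(rlnorm(50), paste0("g", 1:50)))
  qs <- seq(0.1, 0.6, by = 0.05)
  expect_true(all(diff(vapply(qs, function(q) fpkm_threshold(p2, q),
                              numeric(1))) >= 0))
})

test_that("reaction expression: AND takes min, OR takes max, no-data is transparent", {
  p <- expression_profile("t", c(g1 = 10, g2 = 2))
  expect_equal(reaction_expression("g1 and g2", p), 2)
  expect_equal(reaction_expression("g1 or g2", p), 10)
  expect_equal(reaction_expression("g1 and gX", p), 10)   # gX has no data
  expect_equal(reaction_expression("g2 or gX", p), 2)
  expect_true(is.na(reaction_expression("", p)))          # orphan
  expect_true(is.na(reaction_expression("gX and gY", p)))
})

test_that("GIMME reroutes flux through the expressed path in a two-path toy", {
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_hb3_e", -10)
  profs <- make_expression_profiles(
    m, list(off_gcs = "gcsA_toy", off_none = character(0)), seed = 11)
  cm <- build_condition_model(m, profs$off_gcs, med)
  expect_identical(cm$flagged, "GCS")
  expect_identical(cm$removed, "GCS")
  expect_gte(cm$objective_value, 0.9 * cm$parent_objective - 1e-9)
  # flux now goes through the glyoxylate-shunt routing only
  sol <- solve_fba(cm$model, med, parsimonious = TRUE)
  expect_equal(unname(sol$fluxes["GCS"]), 0)
  expect_gt(sol$fluxes[["ICL"]], 1e-6)
  # enumerate both routings: the chosen one carries zero penalty flux
  sol_parent <- solve_fba(m, med, parsimonious = TRUE)
  expect_gt(sol_parent$objective_value + 1e-9, cm$objective_value)
  # empty off-set: condition model is the parent
  cm0 <- build_condition_model(m, profs$off_none, med)
  expect_length(cm0$flagged, 0)
  expect_length(cm0$removed, 0)
  expect_equal(cm0$objective_value, cm0$parent_objective, tolerance = 1e-9)
})

test_that("raising the quantile never shrinks the flagged set", {
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_hb3_e", -10)
  profs <- make_expression_profiles(m, list(c1 = c("gcsA_toy", "glkA_toy")),
                                    seed = 5)
  flags <- lapply(c(0.25, 0.4, 0.6), function(q)
    build_condition_model(m, profs$c1, med, quantile = q,
                          required_objective_fraction = 0.5)$flagged)
  expect_true(all(flags[[1]] %in% flags[[2]]))
  expect_true(all(flags[[2]] %in% flags[[3]]))
})

test_that("conditional essentiality matches unconditional with all-high expression", {
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_ttl_e", -10)
  profs <- make_expression_profiles(m, list(allhigh = character(0)), seed = 2)
  cm <- build_condition_model(m, profs$allhigh, med)
  a <- gene_deletion_screen(m, med)
  b <- conditional_essentiality(cm, med)
  expect_identical(stats::setNames(a$essential, a$gene),
                   stats::setNames(b$essential, b$gene))
})

test_that("aceA becomes essential only in the condition model without the alternative route", {
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_ttl_e", -10)
  # parent: two routes to the gluconeogenic precursor, aceA dispensable
  parent <- gene_deletion_screen(m, med, genes = "aceA_toy")
  expect_false(parent$essential)
  # condition data switch the alternative route off: aceA now essential
  profs <- make_expression_profiles(m, list(tet = "gcsA_toy"), seed = 9)
  cm <- build_condition_model(m, profs$tet, med)
  cond <- conditional_essentiality(cm, med, genes = "aceA_toy")
  expect_true(cond$essential)
})

test_that("hit-and-run samples a 1-D flux segment uniformly", {
  m <- chain_model(lb_ex = -10, ub_ex = 0)   # uptake 0..10, throughput 0..10
  m$reactions$ub[m$reactions$id != "EX_s_e"] <- 10
  sm <- sample_flux_space(m, medium = NULL, n_samples = 5000, seed = 17,
                          warmup = 200, thinning = 2)
  v <- sm[, "BIOMASS_aerobic"]
  se <- stats::sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 5), 3 * se)
  expect_gt(stats::sd(v), 2.0)   # uniform on [0,10] has sd ~ 2.89
  # every sample is feasible
  S <- as.matrix(build_stoichiometric_matrix(m))
  expect_lt(max(abs(S %*% t(sm))), 1e-6)
  expect_true(all(sm[, "EX_s_e"] >= -10 - 1e-9 & sm[, "EX_s_e"] <= 1e-9))
  expect_true(all(sm[, c("St", "BIOMASS_aerobic")] >= -1e-9 &
                    sm[, c("St", "BIOMASS_aerobic")] <= 10 + 1e-9))
  # deterministic given the seed
  sm2 <- sample_flux_space(m, medium = NULL, n_samples = 50, seed = 17,
                           warmup = 200, thinning = 2)
  expect_equal(sm[1:50 * 0 + seq_len(50), , drop = FALSE][1, ], sm2[1, ])
})

test_that("a point polytope yields identical samples", {
  m <- chain_model(lb_ex = -4, ub_ex = -4)
  m$reactions$lb[2:3] <- 4; m$reactions$ub[2:3] <- 4
  sm <- sample_flux_space(m, medium = NULL, n_samples = 20, seed = 1,
                          warmup = 10, thinning = 1)
  expect_lt(max(apply(sm, 2, stats::sd)), 1e-12)
})

test_that("condition models narrow the sampled flux ranges of closed reactions", {
  m <- make_toy_model()
  med <- toy_minimal_medium("EX_hb3_e", -10)
  profs <- make_expression_profiles(m, list(c1 = "gcsA_toy"), seed = 4)
  cm <- build_condition_model(m, profs$c1, med)
  sp <- sample_flux_space(m, med, n_samples = 150, seed = 3, warmup = 150,
                          thinning = 5)
  sc <- sample_flux_space(cm, med, n_samples = 150, seed = 3, warmup = 150,
                          thinning = 5)
  rng <- function(x) diff(range(x))
  expect_gt(rng(sp[, "GCS"]), 0.5)
  expect_equal(rng(sc[, "GCS"]), 0)
  # all condition samples satisfy the steady state
  S <- as.matrix(build_stoichiometric_matrix(cm$model))
  expect_lt(max(abs(S %*% t(sc))), 1e-6)
})

test_that("flux ratios are relative to the carbon uptake", {
  m <- chain_model()
  sol <- solve_fba(m, chain_medium(-8))
  fr <- flux_ratio_map(sol, "EX_s_e")
  expect_equal(unname(fr["EX_s_e"]), 1)
  expect_equal(unname(fr["BIOMASS_aerobic"]), 1)  # 1:1 chain
  # a 70/30 branch gives ratios 0.7/0.3
  mets <- data.frame(id = c("s[e]", "s[c]"), name = "s",
                     compartment = c("e", "c"), stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_s_e", "St", "BR1", "BIOMASS_aerobic"),
                     name = "r", lb = c(-10, 0, 0, 0),
                     ub = c(1000, 7, 1000, 1000), gpr = "",
                     stringsAsFactors = FALSE)
  st <- list(EX_s_e = c("s[e]" = -1), St = c("s[e]" = -1, "s[c]" = 1),
             BR1 = c("s[e]" = -1, "s[c]" = 1),
             BIOMASS_aerobic = c("s[c]" = -1))
  m2 <- metabolic_model(mets, rxns, st,
                        objectives = c(biomass_aerobic = "BIOMASS_aerobic"))
  sol2 <- solve_fba(m2, medium("b", list(EX_s_e = c(-10, 1000)),
                               o2_exchange = "EX_s_e"))
  fr2 <- flux_ratio_map(sol2, "EX_s_e")
  expect_equal(unname(fr2["St"]), 0.7)
  expect_equal(unname(fr2["BR1"]), 0.3)
  expect_error(flux_ratio_map(solve_fba(m, chain_medium(0)), "EX_s_e"),
               "zero")
})
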