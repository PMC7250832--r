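## Synthetic toy network and data generators.  The toy model is a ~30-reaction
## caricature of an oligotrophic degrader's central metabolism: substrate
## funnels that deliver acetyl units plus reducing equivalents (a 3-HB-like C4
## acid, a C10 dicarboxylate funneled through beta-oxidation, a C10
## tetralin-like aromatic whose oxygenases cost extra O2, lactate, and a
## glucose that lacks a transporter), a lumped TCA cycle, a glyoxylate shunt
## as the anaplerotic route (gene aceA_toy), lumped oxidative phosphorylation,
## a nitrate-respiration branch (NO3 -> NO2, one ATP per nitrate), an
## optional PHB storage branch, NGAM, and aerobic/anaerobic biomass
## reactions.  Chemistry uses pseudo-elements C (carbon), N (nitrogen) and R
## (reducing equivalents) with exact integer bookkeeping, so every internal
## reaction is elementally balanced by construction and balance checking is
## meaningful without real biochemistry.

TOY_YIELDS <- list(
  hb3 = c(ac = 2, nadh = 2, o2 = 0, co2 = 0, atp = 0),
  dcn = c(ac = 5, nadh = 6, o2 = 0, co2 = 0, atp = 0),
  ttl = c(ac = 5, nadh = 4, o2 = 2, co2 = 0, atp = 0),
  lac = c(ac = 1, nadh = 0, o2 = 0, co2 = 1, atp = 2))

#' Generate the synthetic toy metabolic model
#'
#' @param include_glyoxylate_shunt include the lumped isocitrate-lyase route
#'   (gene `aceA_toy`) from acetyl units to oxaloacetate.
#' @param include_nitrate_respiration include nitrate reductase
#'   (`narG_toy`), the NO3/NO2 transports and exchanges.
#' @param include_phb_branch include PHB synthesis (`phbA_toy`) and its
#'   demand reaction `DM_phb`.
#' @param include_alt_gluconeogenesis include a second, shunt-independent
#'   route to the gluconeogenic precursor (`gcsA_toy`); switching both this
#'   and the glyoxylate shunt off leaves biomass unmakeable and is an error.
#' @param n_isozyme_pairs 0, 1 or 2 transporter isozyme pairs (1: the
#'   3-HB transporter is an OR pair `hbtA_toy or hbtB_toy`; 2: the
#'   dicarboxylate transporter gets a pair too).
#' @param yields per-substrate funnel stoichiometry: named list of
#'   `c(ac, nadh, o2, co2, atp)` per mole of substrate for `hb3`, `dcn`,
#'   `ttl`, `lac` (`atp` is an activation/transport cost); substrate formulas
#'   are derived from these so the network stays balanced for any choice.
#' @param seed reserved for interface symmetry with the other generators;
#'   the model is fully deterministic.
#' @return a validated `metabolic_model`.
#' @export
make_toy_model <- function(include_glyoxylate_shunt = TRUE,
                           include_nitrate_respiration = TRUE,
                           include_phb_branch = TRUE,
                           include_alt_gluconeogenesis = TRUE,
                           n_isozyme_pairs = 1,
                           yields = TOY_YIELDS,
                           seed = 1L) {
  if (!include_glyoxylate_shunt && !include_alt_gluconeogenesis)
    stop("contradictory switches: no route to the gluconeogenic precursor")

  sub_formula <- function(y)
    formula_string(c(C = unname(2 * y["ac"] + y["co2"]),
                     R = unname(4 * y["ac"] + y["nadh"])))
  mets <- list()
  met <- function(base, comp, name, formula, charge = NA_integer_)
    list(id = paste0(base, "[", comp, "]"), name = name, compartment = comp,
         formula = formula, charge = charge)
  both <- function(base, name, formula) list(met(base, "e", name, formula),
                                             met(base, "c", name, formula))
  mets <- c(
    both("hb3", "3-hydroxybutyrate-like acid", sub_formula(yields$hb3)),
    both("dcn", "decanedioate-like C10 acid", sub_formula(yields$dcn)),
    both("ttl", "tetralin-like C10 aromatic", sub_formula(yields$ttl)),
    both("lac", "lactate", sub_formula(yields$lac)),
    both("glc", "glucose",
         formula_string(c(C = 6, R = unname(2 * (4 * yields$lac["ac"] +
                                                 yields$lac["nadh"]))))),
    both("nh4", "ammonium", "N"),
    both("o2", "oxygen", "."),
    both("co2", "carbon dioxide", "C"),
    both("h2o", "water (redox sink)", "R"),
    both("pi", "phosphate", "."),
    list(met("ac", "c", "acetyl unit", "C2R4"),
         met("oaa", "c", "oxaloacetate-like C4", "C4R6"),
         met("gcp", "c", "gluconeogenic C3 precursor", "C3R5"),
         met("nad", "c", "oxidized redox carrier", "."),
         met("nadh", "c", "reduced redox carrier", "R"),
         met("atp", "c", "ATP equivalent", "."),
         met("adp", "c", "ADP equivalent", ".")))
  if (include_nitrate_respiration)
    mets <- c(mets, both("no3", "nitrate", "N"), both("no2", "nitrite", "NR"))
  if (include_phb_branch)
    mets <- c(mets, list(met("phb", "c", "PHB monomer equivalent", "C4R9")))
  metdf <- do.call(rbind, lapply(mets, function(m)
    as.data.frame(m, stringsAsFactors = FALSE)))

  rx <- list(); st <- list()
  add <- function(id, name, stoich, gpr = "", lb = 0, ub = DEFAULT_UB,
                  subsystem = "", confidence = 4L) {
    rx[[id]] <<- data.frame(id = id, name = name, lb = lb, ub = ub, gpr = gpr,
                            subsystem = subsystem, confidence = confidence,
                            stringsAsFactors = FALSE)
    st[[id]] <<- stoich
  }
  ex <- function(base) add(paste0("EX_", base, "_e"),
                           paste0(base, " exchange"),
                           stats::setNames(-1, paste0(base, "[e]")),
                           subsystem = "exchange", confidence = NA_integer_)
  for (b in c("hb3", "dcn", "ttl", "lac", "glc", "nh4", "o2", "co2",
              "h2o", "pi")) ex(b)
  if (include_nitrate_respiration) for (b in c("no3", "no2")) ex(b)

  tr <- function(base, gpr = "", rev = FALSE, id = paste0(toupper(base), "t"))
    add(id, paste0(base, " transport"),
        stats::setNames(c(-1, 1), paste0(base, c("[e]", "[c]"))), gpr = gpr,
        lb = if (rev) DEFAULT_LB else 0, subsystem = "transport",
        confidence = if (nzchar(gpr)) 3L else 2L)
  hbt_gpr <- if (n_isozyme_pairs >= 1) "hbtA_toy or hbtB_toy" else "hbtA_toy"
  dct_gpr <- if (n_isozyme_pairs >= 2) "dctA_toy or dctB_toy" else "dctA_toy"
  tr("hb3", hbt_gpr)
  tr("dcn", dct_gpr)
  tr("ttl", "thnA1_toy and thnA2_toy")
  tr("lac", "lctP_toy")
  ## glucose deliberately has no transporter: catabolism exists, entry does not
  tr("nh4"); tr("o2"); tr("pi")
  tr("co2", rev = TRUE); tr("h2o", rev = TRUE)
  if (include_nitrate_respiration) {
    tr("no3")
    add("NO2t", "nitrite export",
        c("no2[c]" = -1, "no2[e]" = 1), subsystem = "transport",
        confidence = 2L)
  }

  funnel <- function(base, y) {
    s <- c(stats::setNames(-1, paste0(base, "[c]")),
           "nad[c]" = -unname(y["nadh"]),
           "ac[c]" = unname(y["ac"]),
           "nadh[c]" = unname(y["nadh"]))
    if (y["o2"] > 0) s["o2[c]"] <- -unname(y["o2"])
    if (y["co2"] > 0) s["co2[c]"] <- unname(y["co2"])
    if (y["atp"] > 0) { s["atp[c]"] <- -unname(y["atp"])
                        s["adp[c]"] <- unname(y["atp"]) }
    s[s != 0]
  }
  add("HBD", "3-HB-like catabolism", funnel("hb3", yields$hb3), "hbdA_toy",
      subsystem = "fatty acid catabolism")
  add("BOX", "beta-oxidation-like funnel", funnel("dcn", yields$dcn),
      "boxA_toy", subsystem = "fatty acid catabolism")
  add("THN", "tetralin-like oxygenolytic funnel", funnel("ttl", yields$ttl),
      "thnB_toy", subsystem = "aromatic catabolism")
  add("LDH", "lactate catabolism", funnel("lac", yields$lac), "ldhA_toy",
      subsystem = "central metabolism")
  add("GLK", "glucose catabolism (Embden-Meyerhof-like)",
      c("glc[c]" = -1, "lac[c]" = 2), "glkA_toy",
      subsystem = "central metabolism")
  add("TCA", "lumped TCA cycle (acetyl oxidation)",
      c("ac[c]" = -1, "nad[c]" = -4, "adp[c]" = -1,
        "co2[c]" = 2, "nadh[c]" = 4, "atp[c]" = 1), "tcaA_toy",
      subsystem = "central metabolism")
  if (include_glyoxylate_shunt)
    add("ICL", "glyoxylate shunt (lumped isocitrate lyase + malate synthase)",
        c("ac[c]" = -2, "nad[c]" = -2, "oaa[c]" = 1, "nadh[c]" = 2),
        "aceA_toy", subsystem = "glyoxylate shunt")
  if (include_alt_gluconeogenesis)
    add("GCS", "alternative gluconeogenic condensation",
        c("ac[c]" = -3, "nad[c]" = -2, "gcp[c]" = 2, "nadh[c]" = 2),
        "gcsA_toy", subsystem = "gluconeogenesis")
  add("PPC", "anaplerotic reductive carboxylation from lactate",
      c("lac[c]" = -1, "co2[c]" = -1, "atp[c]" = -1, "nadh[c]" = -2,
        "oaa[c]" = 1, "adp[c]" = 1, "nad[c]" = 2), "ppcA_toy",
      subsystem = "central metabolism")
  add("GND", "gluconeogenesis from oxaloacetate",
      c("oaa[c]" = -1, "nad[c]" = -1, "gcp[c]" = 1, "co2[c]" = 1,
        "nadh[c]" = 1), "gndA_toy", subsystem = "gluconeogenesis")
  add("OXPHOS", "lumped oxidative phosphorylation (P/O = 2)",
      c("nadh[c]" = -2, "o2[c]" = -1, "adp[c]" = -4,
        "nad[c]" = 2, "h2o[c]" = 2, "atp[c]" = 4), "oxpA_toy",
      subsystem = "oxidative phosphorylation")
  if (include_nitrate_respiration)
    add("NAR", "nitrate reductase (respiratory)",
        c("no3[c]" = -1, "nadh[c]" = -1, "adp[c]" = -1,
          "no2[c]" = 1, "nad[c]" = 1, "atp[c]" = 1), "narG_toy",
        subsystem = "nitrate respiration")
  if (include_phb_branch) {
    add("PHB", "PHB monomer synthesis",
        c("ac[c]" = -2, "nadh[c]" = -1, "phb[c]" = 1, "nad[c]" = 1),
        "phbA_toy", subsystem = "PHB storage")
    add("DM_phb", "PHB demand", c("phb[c]" = -1),
        subsystem = "PHB storage", confidence = NA_integer_)
  }
  add("NGAM", "non-growth ATP maintenance",
      c("atp[c]" = -1, "adp[c]" = 1), lb = 0.92, ub = DEFAULT_UB,
      subsystem = "maintenance", confidence = NA_integer_)
  add("BIOMASS_aerobic", "aerobic biomass",
      c("gcp[c]" = -1, "ac[c]" = -1, "nh4[c]" = -0.5, "pi[c]" = -0.1,
        "atp[c]" = -15, "adp[c]" = 15),
      subsystem = "biomass", confidence = NA_integer_)
  add("BIOMASS_anaerobic", "anaerobic biomass (no phosphate-rich inclusions)",
      c("gcp[c]" = -1, "ac[c]" = -1, "nh4[c]" = -0.5,
        "atp[c]" = -12, "adp[c]" = 12),
      subsystem = "biomass", confidence = NA_integer_)

  rxdf <- do.call(rbind, rx)
  rownames(rxdf) <- NULL
  metabolic_model(metdf, rxdf, st,
                  objectives = c(biomass_aerobic = "BIOMASS_aerobic",
                                 biomass_anaerobic = "BIOMASS_anaerobic"),
                  ngam_reaction = "NGAM")
}

#' Minimal medium for the toy model
#'
#' Nutrient uptakes open at -30 mmol/gDW/h (the uptake-unlimited convention
#' for minimal media), the carbon source at `carbon_lb`; anaerobic media swap
#' O2 for nitrate and close the O2 exchange.
#'
#' @param carbon carbon-source exchange id (default `"EX_hb3_e"`).
#' @param carbon_lb carbon uptake bound (default -10).
#' @param aerobic logical.
#' @param ngam optional NGAM override (mmol/gDW/h).
#' @return a [medium()].
#' @export
toy_minimal_medium <- function(carbon = "EX_hb3_e", carbon_lb = -10,
                               aerobic = TRUE, ngam = NULL) {
  b <- list(EX_nh4_e = c(-30, DEFAULT_UB), EX_pi_e = c(-30, DEFAULT_UB),
            EX_h2o_e = c(-30, DEFAULT_UB), EX_co2_e = c(0, DEFAULT_UB))
  b[[carbon]] <- c(carbon_lb, DEFAULT_UB)
  if (aerobic) b$EX_o2_e <- c(-30, DEFAULT_UB)
  else {
    b$EX_o2_e <- c(0, DEFAULT_UB)
    b$EX_no3_e <- c(-30, DEFAULT_UB)
  }
  medium(paste0("toy-minimal-", if (aerobic) "oxic" else "anoxic"),
         b, aerobic = aerobic, o2_exchange = "EX_o2_e", ngam = ngam)
}

#' Generate condition-specific FPKM profiles for the toy model
#'
#' Produces, per condition, a genome-wide profile: `n_background` non-model
#' genes drawn log-normally fix the genome-wide first quartile; model genes
#' listed as "off" for the condition are placed far below that quartile and
#' all other model genes safely above it, so the GIMME flag set is exactly
#' the reactions those off genes disable.
#'
#' @param model the toy `metabolic_model`.
#' @param conditions named list: condition name -> character vector of off
#'   genes (possibly empty).
#' @param n_background number of non-model background genes.
#' @param meanlog,sdlog log-normal FPKM baseline parameters.
#' @param seed RNG seed.
#' @return named list of [expression_profile()]s.
#' @export
make_expression_profiles <- function(model, conditions, n_background = 400,
                                     meanlog = 3, sdlog = 1, seed = 1L) {
  set.seed(seed)
  bg_ids <- sprintf("bg%04d", seq_len(n_background))
  out <- list()
  for (cond in names(conditions)) {
    off <- conditions[[cond]]
    stopifnot(all(off %in% model$genes))
    bg <- stats::rlnorm(n_background, meanlog, sdlog)
    on_genes <- setdiff(model$genes, off)
    on_vals <- exp(meanlog + abs(stats::rnorm(length(on_genes))) * sdlog)
    off_vals <- exp(meanlog - 6 * sdlog -
                      abs(stats::rnorm(length(off))) * sdlog)
    fpkm <- c(stats::setNames(bg, bg_ids),
              stats::setNames(on_vals, on_genes),
              stats::setNames(off_vals, off))
    ## enforce clean separation around the genome-wide first quartile
    for (i in 1:3) {
      thr <- stats::quantile(fpkm, 0.25, type = 7)
      fpkm[off] <- pmin(fpkm[off], thr * 0.3)
      fpkm[on_genes] <- pmax(fpkm[on_genes], thr * 1.5)
    }
    thr <- stats::quantile(fpkm, 0.25, type = 7)
    stopifnot(all(fpkm[off] < thr), all(fpkm[on_genes] > thr))
    out[[cond]] <- expression_profile(cond, fpkm)
  }
  out
}

#' Generate a noisy batch time course from a forward dFBA run
#'
#' Runs [run_dfba()] with the supplied configuration, extends the trajectory
#' flat if the culture stalls (e.g. maintenance becomes unsatisfiable after
#' depletion), and adds Gaussian measurement noise to the tracked
#' concentration.
#'
#' @param model a `metabolic_model`.
#' @param config a [dfba_config()].
#' @param noise_sd measurement noise standard deviation (mM, absolute).
#' @param exchange tracked exchange reported as "the" substrate (default:
#'   the first tracked exchange).
#' @param seed RNG seed.
#' @return list with `concentration` (data.frame `time`, `conc`), `biomass`
#'   (data.frame `time`, `biomass`), `exchange` and `true_uptake` (the
#'   configured uptake bound, mmol/gDW/h).
#' @export
make_batch_timecourse <- function(model, config, noise_sd = 0,
                                  exchange = NULL, seed = 1L) {
  set.seed(seed)
  traj <- run_dfba(model, config)
  tracked <- attr(traj, "tracked")
  exchange <- exchange %||% tracked[1]
  nt <- config$n_steps + 1L
  if (nrow(traj) < nt) {            # stalled culture: flat tail
    last <- traj[nrow(traj), ]
    extra <- last[rep(1, nt - nrow(traj)), ]
    extra$time <- seq(last$time + config$timestep, by = config$timestep,
                      length.out = nt - nrow(traj))
    extra$growth_rate <- 0
    extra[paste0("flux.", tracked)] <- 0
    traj <- rbind(as.data.frame(traj), extra)
  }
  conc <- traj[[exchange]] + stats::rnorm(nrow(traj), 0, noise_sd)
  list(concentration = data.frame(time = traj$time, conc = conc),
       biomass = data.frame(time = traj$time, biomass = traj$biomass),
       exchange = exchange,
       true_uptake = config$uptake_bounds[[exchange]] %||%
         config$medium$bounds[[exchange]][1])
}
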