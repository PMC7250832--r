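## One-command analysis scenarios chaining the package's pieces: growth-rate
## prediction at measured uptakes, carbon/nitrogen source screening, the
## anaerobic dFBA batch, GIMME condition models with sampling and flux
## ratios, essentiality screens, the PHB-demand sweep and the O2-limited
## substrate hierarchy.  Scenarios run on any supplied model; by default they
## run on the synthetic toy network so the whole pipeline works offline.

SCENARIOS <- c("table2_screen", "table3_growth", "anaerobic_dfba",
               "gimme_3hb", "gimme_tetralin", "essentiality_tetralin",
               "phb_sweep", "o2_hierarchy")

#' Configure the analysis pipeline
#'
#' @param model a `metabolic_model`; default: [make_toy_model()].
#' @param model_sheets optional `c(reactions =, metabolites =)` paths to model
#'   sheets; when given they are loaded instead of `model`, and scenarios
#'   report status `"supplementary model not provided"` if the files are
#'   absent.
#' @param substrates named exchange ids for the recurring substrates:
#'   `hb3`, `sebacate`, `tetralin`, `lactate`.
#' @param uptakes named uptake magnitudes (mmol/gDW/h) used by the
#'   growth-prediction and dFBA scenarios.
#' @param expression named list of [expression_profile()]s for the GIMME
#'   scenarios (`cond_3hb`, `cond_tetralin`); generated for the toy model
#'   when omitted.
#' @param seed RNG seed recorded in outputs and used by stochastic steps.
#' @param out_dir directory for TSV/JSON reports; `NULL` skips writing.
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(model = NULL, model_sheets = NULL,
                            substrates = c(hb3 = "EX_hb3_e",
                                           sebacate = "EX_dcn_e",
                                           tetralin = "EX_ttl_e",
                                           lactate = "EX_lac_e"),
                            uptakes = c(sebacate = 1.61, hb3 = 12.95,
                                        lactate = 2.82,
                                        dfba_hb3 = 3, dfba_no3 = 2.82),
                            expression = NULL, seed = 1L, out_dir = NULL) {
  structure(list(model = model, model_sheets = model_sheets,
                 substrates = substrates, uptakes = uptakes,
                 expression = expression, seed = seed, out_dir = out_dir),
            class = "analysis_config")
}

scenario_model <- function(config) {
  if (!is.null(config$model_sheets)) {
    if (!all(file.exists(config$model_sheets))) return(NULL)
    return(read_model_tables(config$model_sheets[["reactions"]],
                             config$model_sheets[["metabolites"]],
                             quiet = TRUE))
  }
  config$model %||% make_toy_model()
}

scenario_write <- function(config, name, tables) {
  if (is.null(config$out_dir)) return(invisible(NULL))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    path <- file.path(config$out_dir, paste0(name, "_", nm, ".tsv"))
    con <- file(path, "w")
    writeLines(sprintf("# %s | scenario %s | seed %d", format(Sys.time()),
                       name, config$seed), con)
    utils::write.table(tables[[nm]], con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  invisible(NULL)
}

#' Run a named analysis scenario
#'
#' @param config an [analysis_config()].
#' @param scenario one of `"table2_screen"`, `"table3_growth"`,
#'   `"anaerobic_dfba"`, `"gimme_3hb"`, `"gimme_tetralin"`,
#'   `"essentiality_tetralin"`, `"phb_sweep"`, `"o2_hierarchy"`.
#' @return list with `scenario`, `status` and scenario-specific results;
#'   TSV reports are written to `config$out_dir` when set.
#' @export
run_scenario <- function(config, scenario) {
  if (!scenario %in% SCENARIOS)
    stop("unknown scenario '", scenario, "'; valid scenarios: ",
         paste(SCENARIOS, collapse = ", "))
  model <- scenario_model(config)
  if (is.null(model))
    return(list(scenario = scenario,
                status = "supplementary model not provided"))
  sub <- config$substrates
  up <- config$uptakes
  res <- switch(scenario,
    table3_growth = {
      rows <- lapply(c("sebacate", "hb3", "lactate"), function(s) {
        sol <- solve_fba(model, toy_minimal_medium(sub[[s]], -up[[s]]))
        data.frame(substrate = s, exchange = sub[[s]], uptake = -up[[s]],
                   growth_rate = sol$objective_value, status = sol$status,
                   stringsAsFactors = FALSE)
      })
      list(growth = do.call(rbind, rows))
    },
    table2_screen = {
      med <- toy_minimal_medium(sub[["hb3"]], -30)
      list(C = screen_sources(model, med, "C", carbon_exchange = sub[["hb3"]]),
           N = screen_sources(model, med, "N", carbon_exchange = sub[["hb3"]]),
           CN = screen_sources(model, med, "CN", carbon_exchange = sub[["hb3"]]))
    },
    anaerobic_dfba = {
      med <- toy_minimal_medium(sub[["hb3"]], -up[["dfba_hb3"]],
                                aerobic = FALSE)
      cfg <- dfba_config(
        initial_biomass = 0.038,
        initial_concentrations = stats::setNames(
          c(40, 20, 0), c(sub[["hb3"]], "EX_no3_e", "EX_no2_e")),
        uptake_bounds = stats::setNames(
          list(-up[["dfba_hb3"]], -up[["dfba_no3"]], 0),
          c(sub[["hb3"]], "EX_no3_e", "EX_no2_e")),
        timestep = 1, n_steps = 200, medium = med)
      traj <- run_dfba(model, cfg)
      no3_used <- traj$EX_no3_e[1] - traj$EX_no3_e
      no2_made <- traj$EX_no2_e - traj$EX_no2_e[1]
      list(trajectory = as.data.frame(traj),
           summary = trajectory_summary(traj),
           max_nitrate_nitrite_imbalance = max(abs(no2_made - no3_used)))
    },
    gimme_3hb = run_gimme_scenario(config, model, "cond_3hb", sub[["hb3"]]),
    gimme_tetralin = run_gimme_scenario(config, model, "cond_tetralin",
                                        sub[["tetralin"]]),
    essentiality_tetralin = {
      med <- toy_minimal_medium(sub[["tetralin"]], -10)
      list(essentiality = gene_deletion_screen(model, med))
    },
    phb_sweep = {
      med <- toy_minimal_medium(sub[["hb3"]], -10)
      base <- solve_fba(model, med)
      list(sweep = phb_demand_sweep(model, med,
                                    seq(0, 2, length.out = 9)))
    },
    o2_hierarchy = {
      med <- toy_minimal_medium(sub[["hb3"]], 0)
      list(hierarchy = substrate_hierarchy(
        model, med, c(sub[["hb3"]], sub[["tetralin"]]), o2_lb = -5))
    })
  tables <- Filter(is.data.frame, res)
  scenario_write(config, scenario, tables)
  c(list(scenario = scenario, status = "ok", seed = config$seed), res)
}

run_gimme_scenario <- function(config, model, cond, carbon_exchange) {
  med <- toy_minimal_medium(carbon_exchange, -10)
  profs <- config$expression
  if (is.null(profs)) {
    off <- list(cond_3hb = c("thnA1_toy", "thnA2_toy", "thnB_toy",
                             "glkA_toy", "gcsA_toy"),
                cond_tetralin = c("hbtA_toy", "hbtB_toy", "glkA_toy",
                                  "gcsA_toy"))
    profs <- make_expression_profiles(model, off[cond], seed = config$seed)
  }
  cm <- build_condition_model(model, profs[[cond]], med)
  sol <- solve_fba(cm$model, med, parsimonious = TRUE)
  ratios <- flux_ratio_map(sol, carbon_exchange)
  samples <- sample_flux_space(cm, med, n_samples = 200,
                               seed = config$seed, warmup = 200, thinning = 20)
  list(condition_model = cm,
       flux_ratios = data.frame(reaction = names(ratios),
                                ratio = unname(ratios)),
       sample_summary = data.frame(
         reaction = colnames(samples),
         mean = colMeans(samples),
         sd = apply(samples, 2, stats::sd)))
}
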