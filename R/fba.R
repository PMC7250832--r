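## Steady-state constraint-based analyses.  FBA maximizes the flux through a
## biomass objective subject to S v = 0 and flux bounds; the medium decides
## which exchange uptakes are open.  Because optimal flux vectors are usually
## degenerate, reported distributions can be post-processed parsimoniously
## (minimum total |v| at the optimal objective, pFBA-style) so that downstream
## flux-ratio maps are reproducible; the objective value itself is always the
## plain FBA optimum.

GROWTH_TOL <- 1e-6

#' Exchange reactions of a model
#' @param model a `metabolic_model`.
#' @return character vector of exchange reaction ids.
#' @export
exchange_ids <- function(model) model$reactions$id[model$reactions$kind == "exchange"]

#' Metabolite moved by a boundary reaction
#' @param model a `metabolic_model`.
#' @param reaction_id boundary (exchange/sink/demand) reaction id.
#' @return metabolite id.
#' @export
boundary_metabolite <- function(model, reaction_id) {
  st <- model$stoichiometry[[reaction_id]]
  if (is.null(st) || length(st) != 1L)
    stop(reaction_id, " is not a single-metabolite boundary reaction")
  names(st)
}

#' Carbon atoms of the metabolite behind an exchange reaction
#' @inheritParams boundary_metabolite
#' @return number of C atoms, or `NA` if the formula is unknown.
#' @export
carbon_count <- function(model, reaction_id) {
  met <- boundary_metabolite(model, reaction_id)
  f <- parse_formula(model$metabolites$formula[model$metabolites$id == met])
  if (length(f) == 1 && is.na(f)) return(NA_real_)
  cc <- unname(f["C"])
  if (is.na(cc)) 0 else cc
}

## Effective bounds for a solve: exchanges reset to (0, 1000) then the medium
## map applied; the NGAM reaction pinned to the medium's maintenance value;
## extra_bounds (a named list of c(lb, ub)) override everything.
effective_bounds <- function(model, medium = NULL, extra_bounds = NULL) {
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  names(lb) <- names(ub) <- model$reactions$id
  if (!is.null(medium)) {
    ex <- exchange_ids(model)
    lb[ex] <- 0
    ub[ex] <- DEFAULT_UB
    for (nm in names(medium$bounds)) {
      if (!(nm %in% model$reactions$id))
        stop("medium references unknown exchange: ", nm)
      lb[nm] <- medium$bounds[[nm]][1]
      ub[nm] <- medium$bounds[[nm]][2]
    }
    if (!medium$aerobic && medium$o2_exchange %in% names(lb))
      lb[medium$o2_exchange] <- max(lb[medium$o2_exchange], 0)
    if (!is.na(model$ngam_reaction)) {
      ## maintenance is a floor, not a pin: excess ATP may dissipate
      ngam <- medium$ngam %||%
        (if (medium$aerobic) model$ngam_aerobic else model$ngam_anaerobic)
      lb[model$ngam_reaction] <- ngam
      ub[model$ngam_reaction] <- max(ub[model$ngam_reaction], DEFAULT_UB)
    }
  }
  for (nm in names(extra_bounds)) {
    if (!(nm %in% model$reactions$id))
      stop("extra_bounds references unknown reaction: ", nm)
    lb[nm] <- extra_bounds[[nm]][1]
    ub[nm] <- extra_bounds[[nm]][2]
  }
  list(lb = lb, ub = ub)
}

#' Flux balance analysis
#'
#' Maximizes the named objective flux subject to steady state (`S v = 0`) and
#' the bounds implied by the model, the medium and any explicit overrides.
#'
#' @param model a `metabolic_model`.
#' @param medium a [medium()]; `NULL` uses the model's stored bounds as-is.
#' @param objective name in `model$objectives` (default `"biomass_aerobic"`,
#'   or `"biomass_anaerobic"` when the medium is anaerobic and the model has
#'   one).
#' @param extra_bounds named list of `c(lb, ub)` overrides by reaction id.
#' @param parsimonious also minimize total absolute flux at the optimal
#'   objective value (pFBA-style) so the reported flux vector is a unique
#'   representative of the degenerate optimum.
#' @return a `flux_solution`: list with `status`, `objective_value`,
#'   `objective` (reaction id) and named `fluxes` (mmol/gDW/h; the biomass
#'   flux is the specific growth rate in 1/h).
#' @export
solve_fba <- function(model, medium = NULL, objective = NULL,
                      extra_bounds = NULL, parsimonious = FALSE) {
  if (is.null(objective)) {
    objective <- if (!is.null(medium) && !medium$aerobic &&
                     "biomass_anaerobic" %in% names(model$objectives))
      "biomass_anaerobic" else "biomass_aerobic"
  }
  if (!(objective %in% names(model$objectives)))
    stop("unknown objective: ", objective)
  obj_rxn <- model$objectives[[objective]]
  S <- as.matrix(build_stoichiometric_matrix(model))
  bb <- effective_bounds(model, medium, extra_bounds)
  n <- ncol(S)
  cvec <- numeric(n)
  cvec[match(obj_rxn, colnames(S))] <- 1
  res <- lp_solve(cvec, S, lb = bb$lb, ub = bb$ub, maximize = TRUE)
  if (res$status != "optimal")
    return(structure(list(status = res$status, objective_value = NA_real_,
                          objective = obj_rxn, fluxes = NULL),
                     class = "flux_solution"))
  v <- stats::setNames(res$x, colnames(S))
  objval <- res$objval
  if (parsimonious) {
    v2 <- pfba_vector(S, bb$lb, bb$ub, cvec, objval)
    if (!is.null(v2)) v <- stats::setNames(v2, colnames(S))
  }
  structure(list(status = "optimal", objective_value = objval,
                 objective = obj_rxn, fluxes = v),
            class = "flux_solution")
}

## minimum-total-|v| flux vector at a fixed objective value: variables
## (v, p, q) with v = p - q, p,q >= 0; rows S v = 0, v - p + q = 0, c'v = z*.
pfba_vector <- function(S, lb, ub, cvec, objval, slack = 1e-9) {
  m <- nrow(S); n <- ncol(S)
  A <- rbind(cbind(S, matrix(0, m, 2 * n)),
             cbind(diag(n), -diag(n), diag(n)),
             c(cvec, numeric(2 * n)))
  rhs <- c(numeric(m + n), objval - slack)
  dir <- c(rep("=", m + n), ">=")
  big <- max(abs(c(lb, ub))) + 1
  res <- lp_solve(c(numeric(n), rep(1, 2 * n)), A, rhs, dir,
                  lb = c(lb, numeric(2 * n)),
                  ub = c(ub, rep(big, 2 * n)),
                  maximize = FALSE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("FBA solution:", x$status)
  if (x$status == "optimal")
    cat(sprintf("; objective (%s) = %.6g", x$objective, x$objective_value))
  cat("\n")
  invisible(x)
}

#' @export
summary.flux_solution <- function(object, ...) {
  if (object$status != "optimal") return(print(object))
  cat(sprintf("objective (%s) = %.6g\n", object$objective,
              object$objective_value))
  act <- object$fluxes[abs(object$fluxes) > 1e-9]
  cat(length(act), "reactions carry flux; largest:\n")
  print(utils::head(sort(abs(act), decreasing = TRUE), 10))
  invisible(object)
}

#' Screen exchange metabolites as carbon and/or nitrogen sources
#'
#' Each candidate exchange is opened at an uptake of `uptake` (default -10
#' mmol/gDW/h) while every other nutrient of the minimal medium, including
#' oxygen, is allowed up to `background_lb` (default -30). Depending on
#' `role`, the medium's default carbon source (`"C"`), its ammonium source
#' (`"N"`), or both (`"CN"`) are removed from the background first. For
#' carbon roles the growth rate is also normalized by the candidate's carbon
#' count.
#'
#' @param model a `metabolic_model`.
#' @param base_medium the minimal [medium()] (must contain the default carbon
#'   and nitrogen exchanges).
#' @param role `"C"`, `"N"` or `"CN"`.
#' @param candidates exchange ids to test (default: all exchanges).
#' @param carbon_exchange,nitrogen_exchange ids of the background carbon and
#'   nitrogen sources removed according to `role`.
#' @param uptake candidate uptake bound.
#' @param background_lb uptake bound applied to the remaining nutrients.
#' @return data.frame (`exchange`, `role`, `growth_rate`, `grows`,
#'   `growth_per_carbon`).
#' @export
screen_sources <- function(model, base_medium, role = c("C", "N", "CN"),
                           candidates = NULL,
                           carbon_exchange, nitrogen_exchange = "EX_nh4_e",
                           uptake = -10, background_lb = -30) {
  role <- match.arg(role)
  if (is.null(candidates)) candidates <- exchange_ids(model)
  drop <- character(0)
  if (role %in% c("C", "CN")) drop <- c(drop, carbon_exchange)
  if (role %in% c("N", "CN")) drop <- c(drop, nitrogen_exchange)
  background <- setdiff(names(base_medium$bounds), drop)
  bg_bounds <- stats::setNames(
    lapply(background, function(nm) c(background_lb, DEFAULT_UB)), background)
  out <- lapply(candidates, function(ex) {
    med <- medium(paste0(base_medium$name, "+", ex),
                  c(bg_bounds, stats::setNames(list(c(uptake, DEFAULT_UB)), ex)),
                  aerobic = base_medium$aerobic,
                  o2_exchange = base_medium$o2_exchange,
                  ngam = base_medium$ngam)
    sol <- solve_fba(model, med)
    g <- if (sol$status == "optimal") sol$objective_value else 0
    gpc <- NA_real_
    if (role %in% c("C", "CN")) {
      cc <- carbon_count(model, ex)
      if (is.na(cc)) warning("unknown formula for ", ex,
                             "; growth_per_carbon unset")
      else if (cc > 0) gpc <- g / cc
    }
    data.frame(exchange = ex, role = role, growth_rate = g,
               grows = g > GROWTH_TOL, growth_per_carbon = gpc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Fit an uptake rate to an observed growth rate
#'
#' Finds, by bisection, the smallest uptake magnitude `u` such that FBA
#' growth with the exchange's lower bound at `-u` matches `target_growth`.
#' Growth must be monotone non-decreasing in `u` (probed at the bracket
#' ends).
#'
#' @param model a `metabolic_model`.
#' @param medium the base [medium()] (the fitted exchange need not be open in
#'   it).
#' @param exchange_id exchange whose uptake is fitted.
#' @param target_growth observed growth rate (1/h).
#' @param tol growth tolerance for convergence.
#' @param u_max largest uptake magnitude considered.
#' @param objective objective name passed to [solve_fba()].
#' @return the uptake magnitude (mmol/gDW/h, positive; the applied bound is
#'   its negative).
#' @export
fit_uptake_to_growth <- function(model, medium, exchange_id, target_growth,
                                 tol = 1e-4, u_max = 50, objective = NULL) {
  stopifnot(target_growth >= 0)
  growth_at <- function(u) {
    sol <- solve_fba(model, medium, objective = objective,
                     extra_bounds = stats::setNames(
                       list(c(-u, DEFAULT_UB)), exchange_id))
    if (sol$status == "optimal") sol$objective_value else 0
  }
  g_hi <- growth_at(u_max)
  if (g_hi < target_growth - tol) stop("target growth unreachable at uptake ",
                                       u_max)
  lo <- 0; hi <- u_max
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (growth_at(mid) >= target_growth - tol * 0.5) hi <- mid else lo <- mid
    if (hi - lo < 1e-9) break
  }
  hi
}

#' Single-gene deletion (essentiality) screen
#'
#' For each gene, every reaction whose GPR evaluates FALSE with that gene
#' deleted is closed (bounds 0, 0) and FBA is re-solved. A gene is essential
#' when deletion growth falls below the absolute threshold `1e-6` 1/h.
#'
#' @param model a `metabolic_model`.
#' @param medium growth [medium()].
#' @param genes genes to screen (default: all model genes).
#' @param objective objective name passed to [solve_fba()].
#' @param extra_bounds additional bound overrides applied to every solve.
#' @return data.frame (`gene`, `wt_growth`, `deletion_growth`, `essential`).
#' @export
gene_deletion_screen <- function(model, medium, genes = NULL,
                                 objective = NULL, extra_bounds = NULL) {
  if (is.null(genes)) genes <- model$genes
  wt <- solve_fba(model, medium, objective = objective,
                  extra_bounds = extra_bounds)
  if (wt$status != "optimal") stop("wild-type FBA is ", wt$status)
  trees <- lapply(model$reactions$gpr, parse_gpr)
  res <- lapply(genes, function(g) {
    off <- vapply(trees, function(tr)
      !is.null(tr) && !evaluate_gpr(tr, deleted = g), logical(1))
    if (!any(off)) {
      dg <- wt$objective_value
    } else {
      eb <- c(extra_bounds, stats::setNames(
        rep(list(c(0, 0)), sum(off)), model$reactions$id[off]))
      sol <- solve_fba(model, medium, objective = objective, extra_bounds = eb)
      dg <- if (sol$status == "optimal") sol$objective_value else 0
    }
    data.frame(gene = g, wt_growth = wt$objective_value, deletion_growth = dg,
               essential = dg < GROWTH_TOL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Sweep a storage-polymer demand against growth
#'
#' Pins the demand reaction to each requested flux and records the FBA
#' growth; infeasible demands are recorded with growth `NA`.
#'
#' @param model a `metabolic_model`.
#' @param medium growth [medium()].
#' @param demand_fluxes numeric vector of demand fluxes (mmol/gDW/h).
#' @param demand_reaction id of the demand reaction (default `"DM_phb"`).
#' @param objective objective name passed to [solve_fba()].
#' @return data.frame (`demand`, `growth`, `status`).
#' @export
phb_demand_sweep <- function(model, medium, demand_fluxes,
                             demand_reaction = "DM_phb", objective = NULL) {
  out <- lapply(demand_fluxes, function(d) {
    sol <- solve_fba(model, medium, objective = objective,
                     extra_bounds = stats::setNames(list(c(d, d)),
                                                    demand_reaction))
    data.frame(demand = d,
               growth = if (sol$status == "optimal") sol$objective_value else NA_real_,
               status = sol$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Substrate-use hierarchy under an oxygen limitation
#'
#' Offers several substrates simultaneously under a restricted O2 uptake and
#' reports the FBA-optimal uptake flux of each, using the parsimonious
#' tie-break so the split is a unique representative distribution.
#'
#' @param model a `metabolic_model`.
#' @param medium base [medium()].
#' @param substrates exchange ids made available together.
#' @param o2_lb O2 exchange lower bound (e.g. -5 mmol/gDW/h).
#' @param substrate_lb uptake bound offered for each substrate.
#' @return data.frame (`exchange`, `uptake_flux`, `growth`).
#' @export
substrate_hierarchy <- function(model, medium, substrates, o2_lb,
                                substrate_lb = -10) {
  eb <- stats::setNames(rep(list(c(substrate_lb, DEFAULT_UB)),
                            length(substrates)), substrates)
  eb[[medium$o2_exchange]] <- c(o2_lb, DEFAULT_UB)
  sol <- solve_fba(model, medium, extra_bounds = eb, parsimonious = TRUE)
  if (sol$status != "optimal") stop("hierarchy FBA is ", sol$status)
  data.frame(exchange = substrates,
             uptake_flux = unname(sol$fluxes[substrates]),
             growth = sol$objective_value, stringsAsFactors = FALSE)
}
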