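## Condition-specific model construction from RNA-seq expression (GIMME
## flavour), flux sampling of the constrained space, and flux-ratio maps.
##
## A gene counts as unexpressed in a condition when its FPKM falls below the
## first quartile of the profile's FPKM values (genome-wide by default).
## Reaction-level expression is min over AND branches and max over OR
## branches; genes without data are transparent, and orphan reactions carry
## no data and are never flagged.  Flagged reactions are not removed
## outright: a penalty LP minimizes the total flux they carry while the
## biological objective keeps at least a required fraction of the parent
## optimum, and only flagged reactions idle in that parsimonious solution are
## closed.

#' Expression threshold from an FPKM profile
#'
#' Returns the requested quantile (default: first quartile) of all FPKM
#' values present in the profile, using linear interpolation between order
#' statistics (`stats::quantile` type 7).
#'
#' @param profile an [expression_profile()].
#' @param quantile quantile in (0, 1); default 0.25.
#' @return the FPKM cut-off.
#' @export
fpkm_threshold <- function(profile, quantile = 0.25) {
  v <- profile$fpkm[!is.na(profile$fpkm)]
  if (!length(v)) stop("empty expression profile")
  if (length(v) < 4) warning("fewer than 4 genes with data; quartile is unstable")
  unname(stats::quantile(v, quantile, type = 7))
}

#' Reaction-level expression from a GPR rule
#'
#' AND nodes take the minimum of their children (a complex is limited by its
#' scarcest subunit), OR nodes the maximum (isozymes add capacity). Genes
#' absent from the profile carry no data and are transparent to both
#' operators; a fully data-less or orphan rule returns `NA`.
#'
#' @param gpr GPR rule string or parsed tree.
#' @param profile an [expression_profile()].
#' @return FPKM value, or `NA` for no data.
#' @export
reaction_expression <- function(gpr, profile) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(NA_real_)
  fp <- profile$fpkm
  rec <- function(node) {
    if (node$op == "gene") {
      if (!(node$gene %in% names(fp))) return(NA_real_)
      return(unname(fp[[node$gene]]))
    }
    vals <- vapply(node$args, rec, numeric(1))
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NA_real_)
    if (node$op == "and") min(vals) else max(vals)
  }
  rec(gpr)
}

#' Build a condition-specific model (GIMME)
#'
#' Reactions whose GPR-level expression falls below [fpkm_threshold()] are
#' flagged; a penalty LP minimizes the summed absolute flux through flagged
#' reactions subject to the objective attaining at least
#' `required_objective_fraction` of the parent optimum on the given medium;
#' flagged reactions carrying no flux in that solution are closed
#' (bounds 0, 0).
#'
#' @param model parent `metabolic_model`.
#' @param profile an [expression_profile()].
#' @param medium growth [medium()].
#' @param quantile expression quantile for the cut-off (default 0.25).
#' @param required_objective_fraction fraction of the parent optimum the
#'   condition model must retain (default 0.9).
#' @param model_genes_only compute the quantile over model genes only instead
#'   of the whole table (sensitivity switch).
#' @param objective objective name as in [solve_fba()].
#' @return a `condition_model`: list with the reduced `model`, `condition`,
#'   `fpkm_threshold`, `flagged`, `removed`, `required_objective_fraction`,
#'   `parent_objective` and `objective_value`.
#' @export
build_condition_model <- function(model, profile, medium, quantile = 0.25,
                                  required_objective_fraction = 0.9,
                                  model_genes_only = FALSE, objective = NULL) {
  prof <- profile
  if (model_genes_only) {
    keep <- intersect(names(profile$fpkm), model$genes)
    prof <- expression_profile(profile$condition, profile$fpkm[keep])
  }
  thr <- fpkm_threshold(prof, quantile)
  expr <- vapply(model$reactions$gpr, reaction_expression, numeric(1),
                 profile = profile)
  flagged <- model$reactions$id[!is.na(expr) & expr < thr]

  parent <- solve_fba(model, medium, objective = objective)
  if (parent$status != "optimal") stop("parent FBA is ", parent$status)
  z <- parent$objective_value

  S <- as.matrix(build_stoichiometric_matrix(model))
  bb <- effective_bounds(model, medium)
  n <- ncol(S); m <- nrow(S)
  cvec <- numeric(n)
  cvec[match(parent$objective, colnames(S))] <- 1
  fidx <- match(flagged, colnames(S))
  nf <- length(fidx)
  if (nf) {
    ## variables (v, p, q) with v_f = p_f - q_f on flagged reactions
    P <- matrix(0, nf, n); P[cbind(seq_len(nf), fidx)] <- 1
    A <- rbind(cbind(S, matrix(0, m, 2 * nf)),
               cbind(P, -diag(nf), diag(nf)),
               c(cvec, numeric(2 * nf)))
    rhs <- c(numeric(m + nf), required_objective_fraction * z)
    dir <- c(rep("=", m + nf), ">=")
    big <- max(abs(c(bb$lb, bb$ub))) + 1
    res <- lp_solve(c(numeric(n), rep(1, 2 * nf)), A, rhs, dir,
                    lb = c(bb$lb, numeric(2 * nf)),
                    ub = c(bb$ub, rep(big, 2 * nf)), maximize = FALSE)
    if (res$status != "optimal")
      stop(sprintf(paste0("no flux distribution attains %.2f of the parent ",
                          "optimum; maximum attainable fraction is %.3f"),
                   required_objective_fraction, 1.0))
    v <- res$x[seq_len(n)]
    removed <- flagged[abs(v[fidx]) < 1e-9]
  } else removed <- character(0)

  red <- model
  ri <- match(removed, red$reactions$id)
  red$reactions$lb[ri] <- 0
  red$reactions$ub[ri] <- 0
  check <- solve_fba(red, medium, objective = objective)
  stopifnot(check$status == "optimal",
            check$objective_value >= required_objective_fraction * z - 1e-6)
  structure(list(model = red, condition = profile$condition,
                 fpkm_threshold = thr, flagged = flagged, removed = removed,
                 required_objective_fraction = required_objective_fraction,
                 parent_objective = z,
                 objective_value = check$objective_value),
            class = "condition_model")
}

#' @export
print.condition_model <- function(x, ...) {
  cat("Condition-specific model:", x$condition, "\n")
  cat(sprintf("FPKM cut-off %.4g; %d reactions flagged, %d removed\n",
              x$fpkm_threshold, length(x$flagged), length(x$removed)))
  cat(sprintf("objective %.6g (parent %.6g, required fraction %.2f)\n",
              x$objective_value, x$parent_objective,
              x$required_objective_fraction))
  invisible(x)
}

#' Gene essentiality on a condition-specific model
#'
#' Runs [gene_deletion_screen()] on the reduced model of a
#' [build_condition_model()] result.
#'
#' @param condition_model a `condition_model`.
#' @param medium growth [medium()].
#' @param genes genes to screen (default: all).
#' @param objective objective name.
#' @return data.frame as from [gene_deletion_screen()].
#' @export
conditional_essentiality <- function(condition_model, medium, genes = NULL,
                                     objective = NULL) {
  gene_deletion_screen(condition_model$model, medium, genes = genes,
                       objective = objective)
}

#' Sample the feasible flux space (artificially-centered hit-and-run)
#'
#' Warm-up points are generated by optimizing each reaction flux in both
#' directions; the chain then walks along directions drawn from warm-up
#' points relative to the running sample center, staying inside
#' `{S v = 0, lb <= v <= ub}` exactly (directions lie in the null space of S,
#' steps are clipped to the box).
#'
#' @param model a `metabolic_model` or `condition_model`.
#' @param medium growth [medium()]; `NULL` uses stored bounds.
#' @param n_samples number of samples to return.
#' @param seed RNG seed (mandatory: sampling is stochastic).
#' @param warmup chain steps discarded before recording (default 1000).
#' @param thinning chain steps between recorded samples (default 100).
#' @param extra_bounds bound overrides as in [solve_fba()].
#' @return a `flux_samples` matrix (n_samples x n_reactions) with attributes
#'   `seed`, `warmup`, `thinning`.
#' @export
sample_flux_space <- function(model, medium = NULL, n_samples, seed,
                              warmup = 1000, thinning = 100,
                              extra_bounds = NULL) {
  if (inherits(model, "condition_model")) model <- model$model
  set.seed(seed)
  S <- as.matrix(build_stoichiometric_matrix(model))
  bb <- effective_bounds(model, medium, extra_bounds)
  n <- ncol(S)
  ## warm-up vertices: coordinate minima and maxima
  wp <- matrix(NA_real_, n, 0)
  for (j in seq_len(n)) {
    cvec <- numeric(n); cvec[j] <- 1
    for (mx in c(TRUE, FALSE)) {
      r <- lp_solve(cvec, S, lb = bb$lb, ub = bb$ub, maximize = mx)
      if (r$status != "optimal") stop("flux space is ", r$status)
      wp <- cbind(wp, r$x)
    }
  }
  center <- rowMeans(wp)
  x <- center
  total <- warmup + n_samples * thinning
  out <- matrix(NA_real_, n_samples, n, dimnames = list(NULL, colnames(S)))
  kept <- 0L
  nseen <- 1
  for (it in seq_len(total)) {
    w <- wp[, sample.int(ncol(wp), 1L)]
    d <- w - center
    nd <- sqrt(sum(d * d))
    if (nd > 1e-10) {
      d <- d / nd
      act <- abs(d) > 1e-12
      tlo <- (bb$lb[act] - x[act]) / d[act]
      thi <- (bb$ub[act] - x[act]) / d[act]
      tmin <- max(pmin(tlo, thi))
      tmax <- min(pmax(tlo, thi))
      if (tmax > tmin) x <- x + stats::runif(1, tmin, tmax) * d
    }
    nseen <- nseen + 1
    center <- center + (x - center) / nseen
    if (it > warmup && (it - warmup) %% thinning == 0) {
      kept <- kept + 1L
      out[kept, ] <- x
    }
  }
  structure(out, seed = seed, warmup = warmup, thinning = thinning,
            class = c("flux_samples", class(out)))
}

#' Flux-ratio map relative to the carbon uptake
#'
#' Divides each reaction flux magnitude by the magnitude of the carbon uptake
#' flux, so the uptake reaction itself maps to 1.
#'
#' @param solution an optimal `flux_solution`.
#' @param carbon_exchange_id id of the carbon-source exchange.
#' @param reactions reactions to report (default: all).
#' @return named numeric vector of dimensionless ratios.
#' @export
flux_ratio_map <- function(solution, carbon_exchange_id, reactions = NULL) {
  if (solution$status != "optimal") stop("solution is not optimal")
  up <- abs(solution$fluxes[[carbon_exchange_id]])
  if (up < 1e-9) stop("carbon uptake flux is zero")
  if (is.null(reactions)) reactions <- names(solution$fluxes)
  abs(solution$fluxes[reactions]) / up
}
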