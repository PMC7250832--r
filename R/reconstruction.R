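## Reconstruction utilities: ortholog calling by reciprocal best hits, draft
## projection of donor models through ortholog maps and their merge, biomass
## stoichiometric coefficients computed from genome/proteome sequence, uptake
## rates regressed from batch time courses, and a per-precursor producibility
## report (gap filling itself is a manual curation task; the package only
## reports which biomass precursors the network cannot make).

#' Reciprocal-best-hit ortholog filtering
#'
#' A pair (q, s) is kept iff s is q's best forward hit, q is s's best reverse
#' hit, and both direction rows pass all thresholds: identity >=
#' `min_identity`, coverage >= `min_coverage` (of both query and subject when
#' `coverage_both`), e-value < `max_evalue`. Best hit = lowest e-value,
#' ties broken by identity.
#'
#' @param forward_hits,reverse_hits hit tables as from [read_hits()].
#' @param min_identity,min_coverage,max_evalue thresholds (identity and
#'   coverage inclusive, e-value strict).
#' @param coverage_both require the coverage threshold of query and subject
#'   (`TRUE`, default) or of the query only.
#' @return data.frame (`query`, `subject`) of ortholog pairs.
#' @export
filter_rbh <- function(forward_hits, reverse_hits, min_identity = 40,
                       min_coverage = 80, max_evalue = 1e-20,
                       coverage_both = TRUE) {
  pass <- function(h) {
    ok <- h$pident >= min_identity & h$evalue < max_evalue & h$qcovs >= min_coverage
    if (coverage_both) ok <- ok & h$scovs >= min_coverage
    h[ok, , drop = FALSE]
  }
  best <- function(h) {
    h <- h[order(h$qseqid, h$evalue, -h$pident), , drop = FALSE]
    h[!duplicated(h$qseqid), c("qseqid", "sseqid"), drop = FALSE]
  }
  bf <- best(pass(forward_hits))
  br <- best(pass(reverse_hits))
  rev_best <- stats::setNames(br$sseqid, br$qseqid)
  keep <- !is.na(rev_best[bf$sseqid]) & rev_best[bf$sseqid] == bf$qseqid
  out <- data.frame(query = bf$qseqid[keep], subject = bf$sseqid[keep],
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$query), , drop = FALSE]
}

#' GPR curation filter on alignment statistics
#'
#' Accepts candidate gene-reaction assignments whose best-hit alignment has
#' identity strictly above `min_identity`, coverage of *both* proteins
#' strictly above `min_coverage`, and e-value strictly below `max_evalue`.
#'
#' @param hits data.frame with `pident`, `qcovs`, `scovs`, `evalue` (plus any
#'   identifier columns, which are carried through).
#' @param min_identity,min_coverage,max_evalue thresholds (all strict).
#' @return the accepted subset of `hits`.
#' @export
gpr_curation_filter <- function(hits, min_identity = 30, min_coverage = 70,
                                max_evalue = 1e-5) {
  keep <- hits$pident > min_identity & hits$qcovs > min_coverage &
    hits$scovs > min_coverage & hits$evalue < max_evalue
  hits[keep, , drop = FALSE]
}

## Rewrite a GPR tree over target genes through an ortholog map.  Unmapped
## genes are deleted from the expression: an AND losing a mandatory subunit
## becomes unsatisfiable (FALSE); an OR drops unsatisfiable branches.
## Returns the rewritten tree, NULL for an orphan rule, or FALSE when the
## rule is unsatisfiable.
rewrite_gpr <- function(gpr, ortholog_map) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(NULL)
  rec <- function(node) {
    if (node$op == "gene") {
      tg <- ortholog_map[node$gene]
      if (is.na(tg)) return(FALSE)
      return(list(op = "gene", gene = unname(tg)))
    }
    kids <- lapply(node$args, rec)
    dead <- vapply(kids, isFALSE, logical(1))
    if (node$op == "and") {
      if (any(dead)) return(FALSE)
    } else kids <- kids[!dead]
    if (!length(kids)) return(FALSE)
    if (length(kids) == 1L) return(kids[[1L]])
    list(op = node$op, args = kids)
  }
  rec(gpr)
}

#' Project donor models through ortholog maps and merge the drafts
#'
#' A donor reaction is carried into the draft iff its GPR, rewritten over the
#' target organism's genes (donor genes without an ortholog are deleted from
#' the expression), remains satisfiable; orphan reactions are carried as-is.
#' Reactions sharing an id across donors are merged once, with their
#' rewritten GPRs OR-ed and a provenance label; id collisions with
#' conflicting stoichiometry are an error.
#'
#' @param donor_models list of `metabolic_model`s.
#' @param ortholog_maps list (same length) of named character vectors,
#'   donor gene -> target gene.
#' @param donor_names labels used in provenance (default `donor-1`, ...).
#' @return a draft `metabolic_model` with a `provenance` element (named
#'   character: reaction id -> donor label or `"both"`).
#' @export
project_and_merge <- function(donor_models, ortholog_maps,
                              donor_names = paste0("donor-", seq_along(donor_models))) {
  stopifnot(length(donor_models) == length(ortholog_maps))
  rxns <- list(); stoich <- list(); prov <- character(0)
  mets <- NULL
  for (k in seq_along(donor_models)) {
    dm <- donor_models[[k]]
    map <- ortholog_maps[[k]]
    for (i in seq_len(nrow(dm$reactions))) {
      rw <- rewrite_gpr(dm$reactions$gpr[i], map)
      if (isFALSE(rw)) next
      rid <- dm$reactions$id[i]
      st <- dm$stoichiometry[[rid]]
      new_gpr <- gpr_string(if (is.null(rw)) "" else rw)
      if (rid %in% names(stoich)) {
        old <- stoich[[rid]]
        same <- length(old) == length(st) &&
          setequal(names(old), names(st)) &&
          all(abs(old[names(st)] - st) < 1e-9)
        if (!same)
          stop("conflicting stoichiometry for reaction ", rid, ": [",
               reaction_formula_string(old), "] vs [",
               reaction_formula_string(st), "]")
        prov[rid] <- "both"
        og <- rxns[[rid]]$gpr
        if (nzchar(new_gpr) && nzchar(og) && new_gpr != og)
          rxns[[rid]]$gpr <- gpr_string(paste0("(", og, ") or (", new_gpr, ")"))
      } else {
        row <- dm$reactions[i, , drop = FALSE]
        row$gpr <- new_gpr
        rxns[[rid]] <- row
        stoich[[rid]] <- st
        prov[rid] <- donor_names[k]
      }
    }
    keep_mets <- dm$metabolites[dm$metabolites$id %in%
                                 unique(unlist(lapply(stoich, names))), ,
                               drop = FALSE]
    mets <- if (is.null(mets)) keep_mets else
      rbind(mets, keep_mets[!(keep_mets$id %in% mets$id), , drop = FALSE])
  }
  rx <- do.call(rbind, rxns)
  rownames(rx) <- NULL
  mets <- mets[mets$id %in% unique(unlist(lapply(stoich, names))), , drop = FALSE]
  objs <- donor_models[[1]]$objectives
  objs <- objs[objs %in% rx$id]
  if (!length(objs)) objs <- c(draft = rx$id[1])
  draft <- metabolic_model(mets, rx, stoich, objectives = objs,
                           validate = FALSE)
  draft$provenance <- prov
  draft
}

## ---- biomass coefficients --------------------------------------------------

## average residue masses (monomer minus water, g/mol) so that polymer mass
## closure is exact under condensation
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
DNTP_RESIDUE_MASS <- c(dATP = 313.21, dCTP = 289.18, dGTP = 329.21, dTTP = 304.20)
NTP_RESIDUE_MASS <- c(ATP = 329.21, CTP = 305.18, GTP = 345.21, UTP = 306.17)

#' Default macromolecular mass fractions (g/gDW)
#'
#' Standard gram-negative composition used when organism-specific
#' measurements are unavailable; fractions sum to 1.
#' @export
default_mass_fractions <- function() {
  c(protein = 0.55, rna = 0.205, dna = 0.031, lipid = 0.095,
    murein = 0.03, ions = 0.01, soluble = 0.079)
}

#' Biomass stoichiometric coefficients from genome and proteome sequence
#'
#' Amino-acid coefficients are proportional to residue frequency across the
#' proteome, scaled so their residue-mass-weighted sum equals the protein
#' fraction; dNTP coefficients come from genome base composition counted on
#' both strands (DNA fraction); NTP coefficients use the coding-strand
#' composition as a transcript proxy (RNA fraction; an expression-weighted
#' mode can be had by passing a weighted `genome`). Lipid, murein, ions and
#' soluble-pool classes are carried as lumped species, with a sphinganine
#' precursor split out of the lipid fraction (sphingolipid envelope; no LPS).
#' Growth-associated maintenance appends ATP + H2O -> ADP + Pi at `gam`.
#'
#' @param proteome path to a protein FASTA (or an `AAStringSet`).
#' @param genome path to a nucleotide FASTA (or a `DNAStringSet`).
#' @param mass_fractions named g/gDW fractions as in
#'   [default_mass_fractions()]; must sum to 1 within 0.01.
#' @param gam growth-associated maintenance (mmol ATP/gDW, default 40).
#' @param sphinganine_share share of the lipid fraction carried by the
#'   sphinganine precursor (default 0.1).
#' @return a `biomass_composition`: per-monomer coefficients (mmol/gDW) by
#'   class, the mass fractions, lumped-species coefficients and `gam`.
#' @export
biomass_coefficients <- function(proteome, genome,
                                 mass_fractions = default_mass_fractions(),
                                 gam = 40, sphinganine_share = 0.1) {
  if (abs(sum(mass_fractions) - 1) > 0.01)
    stop("mass fractions must sum to 1 (got ", sum(mass_fractions), ")")
  if (is.character(proteome)) proteome <- Biostrings::readAAStringSet(proteome)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (!length(proteome)) stop("empty proteome FASTA")
  if (!length(genome)) stop("empty genome FASTA")

  aa_counts <- colSums(Biostrings::letterFrequency(proteome,
                                                   names(AA_RESIDUE_MASS)))
  if (sum(aa_counts) == 0) stop("no standard amino acids in proteome")
  scale_class <- function(counts, masses, fraction) {
    denom <- sum(counts * masses)       # g/mol-weighted residue count
    if (denom == 0) return(stats::setNames(numeric(length(counts)),
                                           names(counts)))
    1000 * fraction * counts / denom    # mmol/gDW
  }
  aa <- scale_class(aa_counts, AA_RESIDUE_MASS, mass_fractions[["protein"]])

  base <- colSums(Biostrings::letterFrequency(genome, c("A", "C", "G", "T")))
  dntp_counts <- c(dATP = base[["A"]] + base[["T"]],
                   dCTP = base[["C"]] + base[["G"]],
                   dGTP = base[["G"]] + base[["C"]],
                   dTTP = base[["T"]] + base[["A"]])
  dntp <- scale_class(dntp_counts, DNTP_RESIDUE_MASS, mass_fractions[["dna"]])

  ntp_counts <- c(ATP = base[["A"]], CTP = base[["C"]],
                  GTP = base[["G"]], UTP = base[["T"]])
  ntp <- scale_class(ntp_counts, NTP_RESIDUE_MASS, mass_fractions[["rna"]])

  SPHINGANINE_MASS <- 301.51            # C18H39NO2
  lumped_masses <- c(lipid = 700, murein = 194.18, ions = 100, soluble = 250)
  lipid_frac <- mass_fractions[["lipid"]]
  lumped <- c(
    sphinganine = 1000 * lipid_frac * sphinganine_share / SPHINGANINE_MASS,
    lipid = 1000 * lipid_frac * (1 - sphinganine_share) / lumped_masses[["lipid"]],
    murein = 1000 * mass_fractions[["murein"]] / lumped_masses[["murein"]],
    ions = 1000 * mass_fractions[["ions"]] / lumped_masses[["ions"]],
    soluble = 1000 * mass_fractions[["soluble"]] / lumped_masses[["soluble"]])
  structure(list(amino_acids = aa, dntps = dntp, ntps = ntp, lumped = lumped,
                 lumped_masses = c(sphinganine = SPHINGANINE_MASS,
                                   lumped_masses),
                 mass_fractions = mass_fractions, gam = gam),
            class = "biomass_composition")
}

#' Mass closure of a biomass composition
#'
#' @param bc a `biomass_composition`.
#' @return named vector of per-class masses (mg/gDW) plus `total`; exact
#'   closure means total = 1000 mg/gDW.
#' @export
biomass_mass_closure <- function(bc) {
  cls <- c(protein = sum(bc$amino_acids * AA_RESIDUE_MASS),
           dna = sum(bc$dntps * DNTP_RESIDUE_MASS),
           rna = sum(bc$ntps * NTP_RESIDUE_MASS),
           lipid = bc$lumped[["sphinganine"]] * bc$lumped_masses[["sphinganine"]] +
             bc$lumped[["lipid"]] * bc$lumped_masses[["lipid"]],
           murein = bc$lumped[["murein"]] * bc$lumped_masses[["murein"]],
           ions = bc$lumped[["ions"]] * bc$lumped_masses[["ions"]],
           soluble = bc$lumped[["soluble"]] * bc$lumped_masses[["soluble"]])
  c(cls, total = sum(cls))
}

#' @export
print.biomass_composition <- function(x, ...) {
  cl <- biomass_mass_closure(x)
  cat("Biomass composition (mmol/gDW coefficients)\n")
  cat(sprintf("mass closure: %.1f mg/gDW (target 1000)\n", cl[["total"]]))
  cat("top amino acids:\n")
  print(round(utils::head(sort(x$amino_acids, decreasing = TRUE), 5), 4))
  invisible(x)
}

#' Render a biomass composition as a model-sheet reaction row
#'
#' @param bc a `biomass_composition`.
#' @param id reaction id (default `"BIOMASS_synth"`).
#' @param compartment compartment tag for the precursor species.
#' @return one-row data.frame in the reaction-sheet layout.
#' @export
biomass_reaction_row <- function(bc, id = "BIOMASS_synth", compartment = "c") {
  tag <- function(x) paste0(tolower(x), "[", compartment, "]")
  st <- c(-bc$amino_acids, -bc$dntps, -bc$ntps, -bc$lumped)
  names(st) <- tag(names(st))
  st[tag("atp")] <- -bc$gam
  st[tag("h2o")] <- -bc$gam
  st[tag("adp")] <- bc$gam
  st[tag("pi")] <- bc$gam
  st <- st[st != 0]
  data.frame(id = id, name = "biomass from genome-derived coefficients",
             formula = reaction_formula_string(st), gpr = "", subsystem = "biomass",
             lower_bound = "0", upper_bound = "1000", confidence = "",
             stringsAsFactors = FALSE)
}

## ---- uptake-rate estimation ------------------------------------------------

#' Estimate a specific uptake rate from batch time courses
#'
#' For a constant specific rate q, dC/dt = q X(t), so C(t) is linear in the
#' cumulative biomass integral \eqn{\int_0^t X d\tau}. The rate is the slope
#' of that regression (trapezoidal integral), negative for consumption, with
#' its standard error.
#'
#' @param concentration data.frame/list with `time` (h) and `conc` (mM).
#' @param biomass data.frame/list with `time` (h) and `biomass` (gDW/L);
#'   interpolated onto the concentration times when the grids differ.
#' @return an `uptake_estimate`: list with `rate` (mmol/gDW/h), `se`,
#'   `fit_window` (h) and the fitted `n` points.
#' @export
estimate_uptake_rate <- function(concentration, biomass) {
  tc <- concentration$time; C <- concentration$conc
  if (length(tc) < 3) stop("need at least 3 time points")
  X <- stats::approx(biomass$time, biomass$biomass, xout = tc, rule = 2)$y
  cumX <- c(0, cumsum(diff(tc) * (utils::head(X, -1) + utils::tail(X, -1)) / 2))
  fit <- stats::lm(C ~ cumX)
  est <- summary(fit)$coefficients["cumX", ]
  structure(list(rate = unname(est["Estimate"]),
                 se = unname(est["Std. Error"]),
                 fit_window = range(tc), n = length(tc)),
            class = "uptake_estimate")
}

#' @export
print.uptake_estimate <- function(x, ...) {
  cat(sprintf("uptake rate %.4g +/- %.2g mmol/gDW/h (n = %d, window %g-%g h)\n",
              x$rate, x$se, x$n, x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

## ---- biomass precursor producibility ---------------------------------------

#' Report unproducible biomass precursors
#'
#' For each metabolite consumed by the objective's biomass reaction, a
#' transient demand reaction is added and maximized; precursors whose maximal
#' demand flux is (numerically) zero cannot be synthesized by the network on
#' the given medium — the places where gap filling is needed.
#'
#' @param model a `metabolic_model`.
#' @param medium growth [medium()].
#' @param objective objective name (default aerobic biomass).
#' @return data.frame (`metabolite`, `max_flux`, `producible`).
#' @export
check_biomass_precursors <- function(model, medium,
                                     objective = "biomass_aerobic") {
  obj_rxn <- model$objectives[[objective]]
  st <- model$stoichiometry[[obj_rxn]]
  precursors <- names(st)[st < 0]
  S <- as.matrix(build_stoichiometric_matrix(model))
  bb <- effective_bounds(model, medium)
  out <- lapply(precursors, function(met) {
    dcol <- numeric(nrow(S)); names(dcol) <- rownames(S)
    dcol[met] <- -1
    ## conserved-moiety carriers (ATP/ADP style) cannot be drained outright:
    ## when the biomass reaction pairs the precursor with a product of equal
    ## magnitude, the producibility demand returns that partner
    partner <- names(st)[st > 0 & abs(st + st[[met]]) < 1e-9]
    if (length(partner)) dcol[partner[1]] <- 1
    S2 <- cbind(S, dcol)
    r <- lp_solve(c(numeric(ncol(S)), 1), S2,
                  lb = c(bb$lb, 0), ub = c(bb$ub, DEFAULT_UB))
    mx <- if (r$status == "optimal") r$objval else 0
    data.frame(metabolite = met, max_flux = mx, producible = mx > GROWTH_TOL,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
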