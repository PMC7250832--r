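# Independent oracles and tiny fixture builders used across the suite.

# Brute-force LP oracle: enumerate all basic solutions (vertices) of
# {A v = 0, lb <= v <= ub} and return the best objective.  Independent of the
# package's simplex path.
bruteforce_lp_max <- function(obj, A, lb, ub) {
  n <- length(obj)
  A <- as.matrix(A)
  r <- qr(A)$rank
  if (r == 0) return(sum(ifelse(obj > 0, ub, lb) * obj))
  best <- -Inf
  subs <- utils::combn(n, r)
  nb_assign <- as.matrix(expand.grid(rep(list(c(0, 1)), n - r)))
  for (k in seq_len(ncol(subs))) {
    B <- subs[, k]
    N <- setdiff(seq_len(n), B)
    AB <- A[, B, drop = FALSE]
    if (qr(AB)$rank < r) next
    for (a in seq_len(nrow(nb_assign))) {
      vN <- ifelse(nb_assign[a, ] == 0, lb[N], ub[N])
      vB <- tryCatch(qr.solve(AB, -A[, N, drop = FALSE] %*% vN),
                     error = function(e) NULL)
      if (is.null(vB)) next
      v <- numeric(n)
      v[N] <- vN
      v[B] <- vB
      if (all(v >= lb - 1e-7 & v <= ub + 1e-7)) best <- max(best, sum(obj * v))
    }
  }
  best
}

# Random small metabolic-like LP: integer stoichiometry, box bounds
# containing 0 (so v = 0 is always feasible).
random_network_lp <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(1:(n - 1), 1)
  list(A = matrix(sample(-2:2, m * n, TRUE), m, n),
       lb = round(runif(n, -5, 0), 1),
       ub = round(runif(n, 0, 5), 1),
       obj = round(runif(n, -2, 2), 2))
}

# Brute-force GPR truth evaluation via full expansion of the tree.
bruteforce_gpr <- function(tree, deleted) {
  if (is.null(tree)) return(TRUE)
  if (tree$op == "gene") return(!(tree$gene %in% deleted))
  vals <- vapply(tree$args, bruteforce_gpr, logical(1), deleted = deleted)
  if (tree$op == "and") all(vals) else any(vals)
}

random_gpr_tree <- function(genes, depth) {
  if (depth == 0 || runif(1) < 0.4)
    return(list(op = "gene", gene = sample(genes, 1)))
  op <- sample(c("and", "or"), 1)
  list(op = op, args = lapply(seq_len(sample(2:3, 1)), function(i)
    random_gpr_tree(genes, depth - 1)))
}

# Minimal linear chain model: substrate exchange -> transport -> biomass with
# yield 1 (growth equals substrate uptake).
chain_model <- function(lb_ex = 0, ub_ex = 1000) {
  mets <- data.frame(id = c("s[e]", "s[c]"), name = c("s", "s"),
                     compartment = c("e", "c"), formula = c("C2", "C2"),
                     stringsAsFactors = FALSE)
  rxns <- data.frame(id = c("EX_s_e", "St", "BIOMASS_aerobic"),
                     name = c("s exchange", "s transport", "biomass"),
                     lb = c(lb_ex, 0, 0), ub = c(ub_ex, 1000, 1000),
                     gpr = c("", "tA", ""), stringsAsFactors = FALSE)
  st <- list(EX_s_e = c("s[e]" = -1),
             St = c("s[e]" = -1, "s[c]" = 1),
             BIOMASS_aerobic = c("s[c]" = -1))
  metabolic_model(mets, rxns, st,
                  objectives = c(biomass_aerobic = "BIOMASS_aerobic"))
}

chain_medium <- function(uptake = -10) {
  medium("chain", list(EX_s_e = c(uptake, 1000)), aerobic = TRUE,
         o2_exchange = "EX_s_e")
}

# Tiny donor models for projection/merging tests; the product metabolite is
# named after the reaction id, so shared ids share stoichiometry across donors.
tiny_donor <- function(rids, genes_by_rxn, shared_met = "x[c]") {
  mets <- data.frame(id = c(shared_met, paste0("m_", rids, "[c]")),
                     name = "m", compartment = "c", stringsAsFactors = FALSE)
  n <- length(rids)
  rxns <- data.frame(id = rids, name = rids, lb = 0, ub = 1000,
                     gpr = genes_by_rxn, kind = "internal",
                     stringsAsFactors = FALSE)
  st <- stats::setNames(lapply(seq_len(n), function(i)
    stats::setNames(c(-1, 1), c(shared_met, paste0("m_", rids[i], "[c]")))), rids)
  metabolic_model(mets, rxns, st, objectives = c(draft = rids[1]),
                  validate = FALSE)
}

write_tmp_fasta <- function(seqs, path) {
  writeLines(unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]]))), path)
  path
}
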