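## Core in-memory representation of a constraint-based metabolic model:
## metabolites (with compartment, elemental formula, charge), reactions (with
## stoichiometry, flux bounds, gene-protein-reaction boolean rules, subsystem,
## confidence), the gene list and named objectives.  The stoichiometric matrix
## S (metabolites x reactions) is assembled on demand as a sparse Matrix.

DEFAULT_UB <- 1000
DEFAULT_LB <- -1000

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`
#'   (one of `"c"`, `"p"`, `"e"`), and optionally `formula` (elemental formula
#'   string, `NA` for unknown) and `charge`.
#' @param reactions data.frame with columns `id`, `name`, `lb`, `ub`, `gpr`
#'   (boolean gene rule as a string, `""` for orphan/spontaneous reactions),
#'   and optionally `subsystem`, `confidence` (integer 1-4 or `NA`) and
#'   `kind` (one of `"internal"`, `"exchange"`, `"sink"`, `"demand"`,
#'   `"biomass"`; inferred when absent).
#' @param stoichiometry named list, one entry per reaction id, each a named
#'   numeric vector of signed coefficients keyed by metabolite id.
#' @param genes character vector of gene ids; defaults to the genes named in
#'   the GPR rules.
#' @param objectives named character vector mapping objective names (at least
#'   `"biomass_aerobic"`) to reaction ids.
#' @param ngam_reaction id of the non-growth ATP maintenance reaction, or
#'   `NA` if absent.
#' @param ngam_aerobic,ngam_anaerobic NGAM flux (mmol/gDW/h) pinned on the
#'   maintenance reaction under oxic / anoxic media.
#' @param validate run [validate_model()] on the result.
#' @return object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry,
                            genes = NULL, objectives,
                            ngam_reaction = NA_character_,
                            ngam_aerobic = 0.92, ngam_anaerobic = 0.15,
                            validate = TRUE) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (is.null(metabolites$formula)) metabolites$formula <- NA_character_
  if (is.null(metabolites$charge)) metabolites$charge <- NA_integer_
  if (is.null(metabolites$name)) metabolites$name <- metabolites$id
  if (is.null(reactions$name)) reactions$name <- reactions$id
  if (is.null(reactions$gpr)) reactions$gpr <- ""
  reactions$gpr[is.na(reactions$gpr)] <- ""
  if (is.null(reactions$subsystem)) reactions$subsystem <- ""
  if (is.null(reactions$confidence)) reactions$confidence <- NA_integer_
  stoichiometry <- stoichiometry[reactions$id]
  if (is.null(reactions$kind)) {
    reactions$kind <- vapply(seq_len(nrow(reactions)), function(i) {
      infer_reaction_kind(reactions$id[i], stoichiometry[[i]],
                          objectives)
    }, character(1))
  }
  if (is.null(genes)) {
    genes <- sort(unique(unlist(lapply(reactions$gpr, gpr_genes))))
  }
  m <- structure(list(
    metabolites = metabolites,
    reactions = reactions,
    stoichiometry = stoichiometry,
    genes = genes,
    objectives = objectives,
    ngam_reaction = ngam_reaction,
    ngam_aerobic = ngam_aerobic,
    ngam_anaerobic = ngam_anaerobic
  ), class = "metabolic_model")
  if (validate) validate_model(m)
  m
}

infer_reaction_kind <- function(id, stoich, objectives) {
  if (id %in% objectives) return("biomass")
  if (length(stoich) == 1L) {
    if (startsWith(id, "EX_")) return("exchange")
    if (startsWith(id, "DM_")) return("demand")
    if (startsWith(id, "SK_") || startsWith(id, "sink_")) return("sink")
    return("exchange")
  }
  "internal"
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, stoichiometry references, bound ordering, GPR gene
#' membership, compartment-tag consistency and boundary-reaction arity.
#' Errors on the first violation; invisibly returns the model when valid.
#'
#' @param model a `metabolic_model`.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites; rxns <- model$reactions
  if (anyDuplicated(mets$id)) stop("duplicate metabolite ids: ",
    paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  if (anyDuplicated(rxns$id)) stop("duplicate reaction ids: ",
    paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "))
  if (!all(mets$compartment %in% c("c", "p", "e")))
    stop("metabolite compartments must be one of c, p, e")
  tag <- sub("^.*\\[([a-z])\\]$", "\\1", mets$id)
  bad <- tag != mets$compartment & grepl("\\[[a-z]\\]$", mets$id)
  if (any(bad)) stop("compartment tag in id disagrees with compartment field: ",
                     paste(mets$id[bad], collapse = ", "))
  if (any(rxns$lb > rxns$ub + 1e-12))
    stop("lower bound exceeds upper bound for: ",
         paste(rxns$id[rxns$lb > rxns$ub + 1e-12], collapse = ", "))
  for (i in seq_len(nrow(rxns))) {
    st <- model$stoichiometry[[rxns$id[i]]]
    if (is.null(st) || !length(st))
      stop("reaction ", rxns$id[i], " has no stoichiometry")
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown))
      stop("reaction ", rxns$id[i], " references unknown metabolites: ",
           paste(unknown, collapse = ", "))
    if (rxns$kind[i] %in% c("exchange", "sink", "demand") && length(st) != 1L)
      stop("boundary reaction ", rxns$id[i], " must touch exactly one metabolite")
    if (rxns$kind[i] == "internal" && length(st) < 2L)
      stop("internal reaction ", rxns$id[i], " must touch at least two metabolites")
    gg <- gpr_genes(rxns$gpr[i])
    miss <- setdiff(gg, model$genes)
    if (length(miss))
      stop("reaction ", rxns$id[i], " GPR references unknown genes: ",
           paste(miss, collapse = ", "))
  }
  if (!length(model$objectives) || is.null(names(model$objectives)))
    stop("model must declare at least one named objective")
  missobj <- setdiff(unname(model$objectives), rxns$id)
  if (length(missobj))
    stop("objective reaction not in model: ", paste(missobj, collapse = ", "))
  if (!is.na(model$ngam_reaction) && !(model$ngam_reaction %in% rxns$id))
    stop("NGAM reaction not in model: ", model$ngam_reaction)
  invisible(model)
}

#' Assemble the stoichiometric matrix
#'
#' Returns the sparse matrix S with one row per metabolite and one column per
#' reaction (in model order); `S[m, r]` is the signed coefficient of
#' metabolite `m` in reaction `r`, so steady state is `S %*% v = 0`.
#'
#' @param model a `metabolic_model`.
#' @return a `dgCMatrix` with dimnames (metabolite ids, reaction ids).
#' @export
build_stoichiometric_matrix <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (j in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[j]]
    ii <- c(ii, match(names(st), met_ids))
    jj <- c(jj, rep.int(j, length(st)))
    xx <- c(xx, unname(st))
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = c(length(met_ids), length(rxn_ids)),
                       dimnames = list(met_ids, rxn_ids))
}

## ---- elemental formulas ----------------------------------------------------

#' Parse an elemental formula string
#'
#' `"C4H6O3"` becomes `c(C = 4, H = 6, O = 3)`. Elements are an upper-case
#' letter optionally followed by a lower-case letter; a missing count means 1.
#' `NA` or `""` parses to `NA` (unknown formula); `"."` denotes the known
#' empty formula (a massless bookkeeping species).
#'
#' @param x formula string.
#' @return named numeric vector, `NA` if unknown.
#' @export
parse_formula <- function(x) {
  if (is.na(x)) return(NA)
  x <- trimws(x)
  if (x == "") return(NA)
  if (x == ".") return(stats::setNames(numeric(0), character(0)))
  parts <- regmatches(x, gregexpr("([A-Z][a-z]?)([0-9]*)", x))[[1]]
  if (!length(parts) || sum(nchar(parts)) != nchar(x))
    stop("cannot parse formula: ", x)
  el <- sub("[0-9]*$", "", parts)
  ct <- as.numeric(ifelse(sub("^[A-Za-z]+", "", parts) == "", "1",
                          sub("^[A-Za-z]+", "", parts)))
  tapply(ct, el, sum)[unique(el)]
}

formula_string <- function(v) {
  if (length(v) == 1 && is.na(v)) return(NA_character_)
  if (!length(v)) return(".")
  paste0(names(v), ifelse(v == 1, "", format(v, trim = TRUE)), collapse = "")
}

#' Check elemental balance of every reaction
#'
#' Internal reactions whose metabolites all carry formulas are classified as
#' balanced or imbalanced by per-element sums; reactions touching a metabolite
#' with an unknown formula are `"unknown-formula"`; exchange, sink, demand and
#' biomass reactions are exempt.
#'
#' @param model a `metabolic_model`.
#' @param tol absolute per-element tolerance.
#' @return a `balance_report`: data.frame (`reaction`, `status`) with the
#'   per-reaction imbalance maps in attribute `"imbalance"`.
#' @export
check_mass_balance <- function(model, tol = 1e-6) {
  forms <- lapply(model$metabolites$formula, parse_formula)
  names(forms) <- model$metabolites$id
  status <- character(nrow(model$reactions))
  imb <- list()
  for (i in seq_len(nrow(model$reactions))) {
    rid <- model$reactions$id[i]
    if (model$reactions$kind[i] != "internal") { status[i] <- "exempt"; next }
    st <- model$stoichiometry[[rid]]
    fs <- forms[names(st)]
    if (any(vapply(fs, function(f) length(f) == 1 && is.na(f), logical(1)))) {
      status[i] <- "unknown-formula"; next
    }
    els <- unique(unlist(lapply(fs, names)))
    sums <- stats::setNames(numeric(length(els)), els)
    for (k in seq_along(st)) {
      f <- fs[[k]]
      if (length(f)) sums[names(f)] <- sums[names(f)] + st[[k]] * f
    }
    off <- sums[abs(sums) > tol]
    if (length(off)) { status[i] <- "imbalanced"; imb[[rid]] <- off }
    else status[i] <- "balanced"
  }
  rep <- data.frame(reaction = model$reactions$id, status = status,
                    stringsAsFactors = FALSE)
  attr(rep, "imbalance") <- imb
  class(rep) <- c("balance_report", "data.frame")
  rep
}

## ---- GPR boolean rules -----------------------------------------------------

#' Parse a gene-protein-reaction rule
#'
#' Grammar: gene tokens (locus-tag syntax, e.g. `SGRAN_2644`), case-insensitive
#' `and` / `or`, parentheses. The empty string denotes an orphan or
#' spontaneous reaction and parses to `NULL`.
#'
#' @param text GPR rule string.
#' @return a tree of nested lists: `list(op = "gene", gene = id)`,
#'   `list(op = "and", args = ...)` or `list(op = "or", args = ...)`;
#'   `NULL` for the empty rule.
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || is.na(text) || !nzchar(trimws(text))) return(NULL)
  toks <- gpr_tokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks; st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop("GPR parse error near '", st$toks[st$pos], "' in: ", text)
  tree
}

gpr_tokenize <- function(text) {
  text <- gsub("(", " ( ", text, fixed = TRUE)
  text <- gsub(")", " ) ", text, fixed = TRUE)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA
gpr_next <- function(st) { t <- gpr_peek(st); st$pos <- st$pos + 1L; t }

gpr_parse_or <- function(st) {
  args <- list(gpr_parse_and(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "or") {
    gpr_next(st)
    args <- c(args, list(gpr_parse_and(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st) {
  args <- list(gpr_parse_atom(st))
  while (!is.na(gpr_peek(st)) && tolower(gpr_peek(st)) == "and") {
    gpr_next(st)
    args <- c(args, list(gpr_parse_atom(st)))
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

gpr_parse_atom <- function(st) {
  t <- gpr_next(st)
  if (is.na(t)) stop("GPR parse error: unexpected end of rule")
  if (t == "(") {
    inner <- gpr_parse_or(st)
    if (!identical(gpr_next(st), ")")) stop("GPR parse error: missing ')'")
    return(inner)
  }
  if (t == ")" || tolower(t) %in% c("and", "or"))
    stop("GPR parse error: unexpected token '", t, "'")
  list(op = "gene", gene = t)
}

#' Render a GPR tree back to its rule string
#' @param gpr tree from [parse_gpr()] (or a string, returned canonicalized).
#' @return canonical rule string (`""` for orphan reactions).
#' @export
gpr_string <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return("")
  rec <- function(node, parent_op) {
    if (node$op == "gene") return(node$gene)
    inner <- vapply(node$args, rec, character(1), parent_op = node$op)
    s <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && parent_op != node$op) paste0("(", s, ")") else s
  }
  rec(gpr, NULL)
}

#' Genes named by a GPR rule
#' @param gpr rule string or parsed tree.
#' @return character vector of gene ids (empty for orphan reactions).
#' @export
gpr_genes <- function(gpr) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(character(0))
  if (gpr$op == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$args, gpr_genes)))
}

#' Evaluate a GPR rule under a set of gene deletions
#'
#' A `gene` leaf is FALSE iff the gene is deleted; `and` is conjunction, `or`
#' disjunction. The empty rule (orphan/spontaneous reaction) is always TRUE:
#' no deletion can switch such a reaction off.
#'
#' @param gpr rule string or parsed tree.
#' @param deleted character vector of deleted gene ids.
#' @param genes optional character vector of known genes; leaves referencing
#'   genes outside it raise an error.
#' @return logical: does the reaction retain enzymatic support?
#' @export
evaluate_gpr <- function(gpr, deleted = character(0), genes = NULL) {
  if (is.character(gpr)) gpr <- parse_gpr(gpr)
  if (is.null(gpr)) return(TRUE)
  if (!is.null(genes)) {
    miss <- setdiff(gpr_genes(gpr), genes)
    if (length(miss)) stop("GPR references unknown genes: ",
                           paste(miss, collapse = ", "))
  }
  rec <- function(node) {
    switch(node$op,
      gene = !(node$gene %in% deleted),
      and = all(vapply(node$args, rec, logical(1))),
      or = any(vapply(node$args, rec, logical(1))))
  }
  rec(gpr)
}

## ---- reaction-formula strings ---------------------------------------------

#' Parse a reaction formula string
#'
#' `"2 a[c] + b[c] -> c[p]"`; `"<=>"` marks a reversible reaction. Either
#' side may be empty (boundary reactions, e.g. `"hb3[e] <=>"`).
#'
#' @param text formula string.
#' @return list with `stoich` (named numeric, negative = consumed) and
#'   `reversible` (logical).
#' @export
parse_reaction_formula <- function(text) {
  text <- trimws(text)
  rev <- grepl("<=>", text, fixed = TRUE)
  sides <- strsplit(text, "<=>|->")[[1]]
  if (!grepl("<=>|->", text)) stop("reaction formula lacks an arrow: ", text)
  lhs <- if (length(sides) >= 1) trimws(sides[1]) else ""
  rhs <- if (length(sides) >= 2) trimws(sides[2]) else ""
  parse_side <- function(s, sign) {
    if (!nzchar(s)) return(numeric(0))
    out <- numeric(0)
    for (term in trimws(strsplit(s, "+", fixed = TRUE)[[1]])) {
      if (!nzchar(term)) next
      mm <- regmatches(term, regexec("^([0-9.]+[eE]?-?[0-9]*)?\\s*(\\S+)$", term))[[1]]
      if (length(mm) != 3 || !nzchar(mm[3]))
        stop("cannot parse reaction term: '", term, "'")
      coef <- if (nzchar(mm[2])) as.numeric(mm[2]) else 1
      if (is.na(coef)) stop("bad coefficient in term: '", term, "'")
      cur <- if (mm[3] %in% names(out)) out[[mm[3]]] else 0
      out[mm[3]] <- cur + sign * coef
    }
    out
  }
  l <- parse_side(lhs, -1)
  r <- parse_side(rhs, +1)
  st <- l
  for (nm in names(r)) {
    cur <- if (nm %in% names(st)) st[[nm]] else 0
    st[nm] <- cur + r[[nm]]
  }
  st <- st[st != 0]
  list(stoich = st, reversible = rev)
}

#' Render a stoichiometry map as a reaction formula string
#' @param stoich named numeric coefficients (negative = consumed).
#' @param reversible use `"<=>"` instead of `"->"`.
#' @return formula string.
#' @export
reaction_formula_string <- function(stoich, reversible = FALSE) {
  fmt <- function(ids, coefs) {
    if (!length(ids)) return("")
    paste(ifelse(abs(coefs) == 1, ids,
                 paste(format(abs(coefs), trim = TRUE, digits = 10), ids)),
          collapse = " + ")
  }
  neg <- stoich < 0
  lhs <- fmt(names(stoich)[neg], stoich[neg])
  rhs <- fmt(names(stoich)[!neg], stoich[!neg])
  trimws(paste(lhs, if (reversible) "<=>" else "->", rhs))
}

## ---- printing --------------------------------------------------------------

#' @export
print.metabolic_model <- function(x, ...) {
  cat("Metabolic model:", nrow(x$reactions), "reactions,",
      nrow(x$metabolites), "metabolites,", length(x$genes), "genes\n")
  cat("Objectives:", paste(names(x$objectives), "->", x$objectives,
                           collapse = "; "), "\n")
  invisible(x)
}

#' Model census: counts and curation statistics
#'
#' @param object a `metabolic_model`.
#' @param ... unused.
#' @return list with reaction/metabolite/gene counts, the number and fraction
#'   of gene-associated reactions and of reactions with confidence 3-4.
#' @export
summary.metabolic_model <- function(object, ...) {
  gpr_assoc <- nzchar(object$reactions$gpr)
  conf <- object$reactions$confidence
  out <- list(
    n_reactions = nrow(object$reactions),
    n_metabolites = nrow(object$metabolites),
    n_genes = length(object$genes),
    n_gene_associated = sum(gpr_assoc),
    pct_gene_associated = 100 * mean(gpr_assoc),
    n_confidence_34 = sum(conf %in% c(3, 4)),
    pct_confidence_34 = 100 * sum(conf %in% c(3, 4)) / nrow(object$reactions),
    kinds = table(object$reactions$kind)
  )
  class(out) <- "summary.metabolic_model"
  out
}

#' @export
print.summary.metabolic_model <- function(x, ...) {
  cat(sprintf("%d reactions, %d metabolites, %d genes\n",
              x$n_reactions, x$n_metabolites, x$n_genes))
  cat(sprintf("gene-associated reactions: %d (%.1f%%)\n",
              x$n_gene_associated, x$pct_gene_associated))
  cat(sprintf("confidence 3-4: %d (%.1f%%)\n",
              x$n_confidence_34, x$pct_confidence_34))
  print(x$kinds)
  invisible(x)
}
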