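## Readers and writers for the package's canonical plain-text formats:
##   - model sheets: two TSV files (reactions, metabolites) with fixed headers
##   - SBML Level 3 Version 1 with the fbc (version 2) extension
##   - medium definitions as YAML/JSON exchange-bound maps
##   - expression tables (gene_id <TAB> fpkm)
##   - BLAST outfmt-6-like ortholog hit tables
## The TSV sheet dialect is the canonical interchange format; both paths
## round-trip models exactly (ids, stoichiometry, bounds, canonical GPRs).

REACTION_SHEET_COLS <- c("id", "name", "formula", "gpr", "subsystem",
                         "lower_bound", "upper_bound", "confidence")
METABOLITE_SHEET_COLS <- c("id", "name", "compartment", "formula", "charge")

#' Read a model from tabular reaction/metabolite sheets
#'
#' The sheets are tab-separated with fixed headers. Reaction sheet columns:
#' `id`, `name`, `formula` (e.g. `"2 a[c] + b[c] -> c[p]"`, `"<=>"` for
#' reversible), `gpr`, `subsystem`, `lower_bound`, `upper_bound`,
#' `confidence`. Empty bounds default to (0, 1000) for `"->"` reactions and
#' (-1000, 1000) for `"<=>"`. Metabolite sheet columns: `id`, `name`,
#' `compartment`, `formula`, `charge`.
#'
#' Objectives are recognized by reaction id: ids starting `BIOMASS` become
#' objectives, named `biomass_anaerobic` when the id contains `anaer` and
#' `biomass_aerobic` otherwise; a reaction with id `NGAM` is registered as the
#' maintenance reaction.
#'
#' @param reaction_sheet,metabolite_sheet paths to the TSV files.
#' @param quiet suppress the load log.
#' @return a validated [metabolic_model()].
#' @export
read_model_tables <- function(reaction_sheet, metabolite_sheet, quiet = FALSE) {
  rt <- utils::read.delim(reaction_sheet, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  mt <- utils::read.delim(metabolite_sheet, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  miss <- setdiff(REACTION_SHEET_COLS, names(rt))
  if (length(miss)) stop("reaction sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(METABOLITE_SHEET_COLS, names(mt))
  if (length(miss)) stop("metabolite sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  if (!nrow(rt)) stop("no reactions in ", reaction_sheet)
  if (!nrow(mt)) stop("no metabolites in ", metabolite_sheet)

  mets <- data.frame(id = mt$id, name = mt$name, compartment = mt$compartment,
                     formula = ifelse(mt$formula == "", NA, mt$formula),
                     charge = suppressWarnings(as.integer(mt$charge)),
                     stringsAsFactors = FALSE)
  stoich <- vector("list", nrow(rt))
  lbs <- ubs <- numeric(nrow(rt))
  for (i in seq_len(nrow(rt))) {
    pf <- tryCatch(parse_reaction_formula(rt$formula[i]), error = function(e)
      stop("reaction sheet row ", i, " (", rt$id[i], "): ", conditionMessage(e)))
    stoich[[i]] <- pf$stoich
    lbs[i] <- if (nzchar(rt$lower_bound[i]))
      as.numeric(rt$lower_bound[i]) else if (pf$reversible) DEFAULT_LB else 0
    ubs[i] <- if (nzchar(rt$upper_bound[i]))
      as.numeric(rt$upper_bound[i]) else DEFAULT_UB
    tryCatch(parse_gpr(rt$gpr[i]), error = function(e)
      stop("reaction sheet row ", i, " (", rt$id[i], "): ", conditionMessage(e)))
  }
  names(stoich) <- rt$id
  if (anyDuplicated(rt$id))
    stop("duplicate reaction ids in sheet: ",
         paste(unique(rt$id[duplicated(rt$id)]), collapse = ", "))
  rxns <- data.frame(id = rt$id, name = rt$name, lb = lbs, ub = ubs,
                     gpr = rt$gpr, subsystem = rt$subsystem,
                     confidence = suppressWarnings(as.integer(rt$confidence)),
                     stringsAsFactors = FALSE)
  biomass_ids <- rt$id[startsWith(rt$id, "BIOMASS")]
  if (!length(biomass_ids)) stop("no BIOMASS reaction found in sheet")
  objectives <- stats::setNames(biomass_ids,
    ifelse(grepl("anaer", biomass_ids, ignore.case = TRUE),
           "biomass_anaerobic", "biomass_aerobic"))
  model <- metabolic_model(mets, rxns, stoich, objectives = objectives,
    ngam_reaction = if ("NGAM" %in% rt$id) "NGAM" else NA_character_)
  if (!quiet)
    message("loaded model: ", nrow(model$reactions), " reactions, ",
            nrow(model$metabolites), " metabolites, ",
            length(model$genes), " genes")
  model
}

#' Write a model to tabular reaction/metabolite sheets
#'
#' @param model a `metabolic_model`.
#' @param reaction_sheet,metabolite_sheet output paths.
#' @return invisibly, the two paths.
#' @export
write_model_tables <- function(model, reaction_sheet, metabolite_sheet) {
  rx <- model$reactions
  fm <- vapply(seq_len(nrow(rx)), function(i)
    reaction_formula_string(model$stoichiometry[[rx$id[i]]],
                            reversible = rx$lb[i] < 0), character(1))
  rt <- data.frame(id = rx$id, name = rx$name, formula = fm,
                   gpr = vapply(rx$gpr, gpr_string, character(1)),
                   subsystem = rx$subsystem,
                   lower_bound = format(rx$lb, trim = TRUE, digits = 12),
                   upper_bound = format(rx$ub, trim = TRUE, digits = 12),
                   confidence = ifelse(is.na(rx$confidence), "",
                                       as.character(rx$confidence)),
                   stringsAsFactors = FALSE)
  mt <- model$metabolites
  mt_out <- data.frame(id = mt$id, name = mt$name, compartment = mt$compartment,
                       formula = ifelse(is.na(mt$formula), "", mt$formula),
                       charge = ifelse(is.na(mt$charge), "",
                                       as.character(mt$charge)),
                       stringsAsFactors = FALSE)
  utils::write.table(rt, reaction_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(mt_out, metabolite_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(reaction_sheet, metabolite_sheet))
}

## ---- SBML L3 + fbc ---------------------------------------------------------

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_met_id <- function(id) {
  base <- sub("\\[([a-z])\\]$", "_\\1", id)
  paste0("M_", gsub("[^A-Za-z0-9_]", "_", base))
}
unsbml_met_id <- function(id, compartment) {
  base <- sub("^M_", "", id)
  base <- sub(paste0("_", compartment, "$"), "", base)
  paste0(base, "[", compartment, "]")
}
sbml_gene_id <- function(g) paste0("G_", gsub("[^A-Za-z0-9_]", "_", g))

#' Write a model as SBML Level 3 with the fbc extension
#'
#' Flux bounds are emitted as shared `parameter` elements referenced through
#' `fbc:lowerFluxBound`/`fbc:upperFluxBound`; GPRs as
#' `fbc:geneProductAssociation` trees; objectives as `fbc:listOfObjectives`
#' with the aerobic biomass active. Subsystem, confidence and the NGAM
#' configuration travel in `notes` key/value paragraphs.
#'
#' @param model a `metabolic_model`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_sbml <- function(model, path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  rx <- model$reactions
  bounds <- sort(unique(c(rx$lb, rx$ub)))
  fmt1 <- function(v) vapply(v, function(x)
    format(x, digits = 12, trim = TRUE), character(1))
  bnd_id <- function(v) paste0("bnd_", gsub("[^0-9A-Za-z]", "_", fmt1(v)))
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf('<sbml xmlns="%s" xmlns:fbc="%s" level="3" version="1" fbc:required="false">',
            SBML_NS, FBC_NS),
    sprintf('<model id="%s" fbc:strict="true">', "model"),
    '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
    sprintf('<p>NGAM_REACTION: %s</p>',
            ifelse(is.na(model$ngam_reaction), "", model$ngam_reaction)),
    sprintf('<p>NGAM_AEROBIC: %s</p>', model$ngam_aerobic),
    sprintf('<p>NGAM_ANAEROBIC: %s</p>', model$ngam_anaerobic),
    '</body></notes>',
    '<listOfCompartments>',
    sprintf('<compartment id="%s" constant="true"/>',
            unique(model$metabolites$compartment)),
    '</listOfCompartments>',
    '<listOfSpecies>')
  mt <- model$metabolites
  for (i in seq_len(nrow(mt))) {
    extra <- ""
    if (!is.na(mt$formula[i]))
      extra <- paste0(extra, sprintf(' fbc:chemicalFormula="%s"',
                                     if (mt$formula[i] == ".") "" else mt$formula[i]))
    if (!is.na(mt$charge[i]))
      extra <- paste0(extra, sprintf(' fbc:charge="%d"', mt$charge[i]))
    lines <- c(lines, sprintf(
      '<species id="%s" name="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"%s/>',
      sbml_met_id(mt$id[i]), esc(mt$name[i]), mt$compartment[i], extra))
  }
  lines <- c(lines, '</listOfSpecies>', '<listOfParameters>',
             sprintf('<parameter id="%s" value="%s" constant="true"/>',
                     bnd_id(bounds), fmt1(bounds)),
             '</listOfParameters>',
             '<fbc:listOfGeneProducts>',
             if (length(model$genes)) sprintf(
               '<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
               sbml_gene_id(model$genes), esc(model$genes)) else character(0),
             '</fbc:listOfGeneProducts>',
             '<listOfReactions>')
  gpa_xml <- function(node) {
    if (node$op == "gene")
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>',
                     sbml_gene_id(node$gene)))
    tag <- if (node$op == "and") "fbc:and" else "fbc:or"
    paste0("<", tag, ">",
           paste(vapply(node$args, gpa_xml, character(1)), collapse = ""),
           "</", tag, ">")
  }
  for (i in seq_len(nrow(rx))) {
    st <- model$stoichiometry[[rx$id[i]]]
    reac <- st[st < 0]; prod <- st[st > 0]
    body <- c(
      '<notes><body xmlns="http://www.w3.org/1999/xhtml">',
      sprintf('<p>SUBSYSTEM: %s</p>', esc(rx$subsystem[i])),
      sprintf('<p>CONFIDENCE: %s</p>',
              ifelse(is.na(rx$confidence[i]), "", rx$confidence[i])),
      sprintf('<p>KIND: %s</p>', rx$kind[i]),
      '</body></notes>')
    if (length(reac))
      body <- c(body, '<listOfReactants>',
        sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                sbml_met_id(names(reac)),
                format(-unname(reac), digits = 12, trim = TRUE)),
        '</listOfReactants>')
    if (length(prod))
      body <- c(body, '<listOfProducts>',
        sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                sbml_met_id(names(prod)),
                format(unname(prod), digits = 12, trim = TRUE)),
        '</listOfProducts>')
    g <- parse_gpr(rx$gpr[i])
    if (!is.null(g))
      body <- c(body, '<fbc:geneProductAssociation>', gpa_xml(g),
                '</fbc:geneProductAssociation>')
    lines <- c(lines, sprintf(
      '<reaction id="R_%s" name="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      rx$id[i], esc(rx$name[i]), tolower(rx$lb[i] < 0),
      bnd_id(rx$lb[i]), bnd_id(rx$ub[i])), body, '</reaction>')
  }
  obj_names <- names(model$objectives)
  active <- if ("biomass_aerobic" %in% obj_names) "biomass_aerobic" else obj_names[1]
  lines <- c(lines, '</listOfReactions>',
    sprintf('<fbc:listOfObjectives fbc:activeObjective="%s">', active),
    unlist(lapply(obj_names, function(nm) c(
      sprintf('<fbc:objective fbc:id="%s" fbc:type="maximize">', nm),
      '<fbc:listOfFluxObjectives>',
      sprintf('<fbc:fluxObjective fbc:reaction="R_%s" fbc:coefficient="1"/>',
              model$objectives[[nm]]),
      '</fbc:listOfFluxObjectives>',
      '</fbc:objective>'))),
    '</fbc:listOfObjectives>', '</model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

#' Read a model from SBML Level 3 with the fbc extension
#'
#' Reactions lacking flux-bound attributes receive the package defaults
#' ((0, 1000) irreversible, (-1000, 1000) when `reversible="true"`) with a
#' warning.
#'
#' @param path SBML file.
#' @param quiet suppress the load log.
#' @return a validated [metabolic_model()].
#' @export
read_sbml <- function(path, quiet = FALSE) {
  doc <- xml2::read_xml(path)
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  xattr <- xml2::xml_attr
  notes_kv <- function(node) {
    ps <- xml2::xml_find_all(node, ".//s:notes//*[local-name()='p']", ns)
    txt <- xml2::xml_text(ps)
    kv <- regmatches(txt, regexec("^([A-Z_]+): ?(.*)$", txt))
    out <- list()
    for (m in kv) if (length(m) == 3) out[[m[2]]] <- m[3]
    out
  }
  mnode <- xml2::xml_find_first(doc, ".//s:model", ns)
  mkv <- notes_kv(mnode)

  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  comp <- xattr(sp, "compartment")
  sids <- xattr(sp, "id")
  mets <- data.frame(
    id = mapply(unsbml_met_id, sids, comp, USE.NAMES = FALSE),
    name = xattr(sp, "name"),
    compartment = comp,
    formula = ifelse(is.na(xattr(sp, "fbc:chemicalFormula", ns)), NA,
                     ifelse(xattr(sp, "fbc:chemicalFormula", ns) == "", ".",
                            xattr(sp, "fbc:chemicalFormula", ns))),
    charge = suppressWarnings(as.integer(xattr(sp, "fbc:charge", ns))),
    stringsAsFactors = FALSE)
  sid_to_met <- stats::setNames(mets$id, sids)

  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  parval <- stats::setNames(as.numeric(xattr(pars, "value")), xattr(pars, "id"))

  gps <- xml2::xml_find_all(doc, ".//fbc:listOfGeneProducts/fbc:geneProduct", ns)
  gid_to_gene <- stats::setNames(xattr(gps, "fbc:label", ns),
                                 xattr(gps, "fbc:id", ns))

  gpa_tree <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef")
      return(list(op = "gene",
                  gene = gid_to_gene[[xattr(node, "fbc:geneProduct", ns)]]))
    kids <- xml2::xml_children(node)
    list(op = if (nm == "and") "and" else "or",
         args = lapply(kids, gpa_tree))
  }

  rnodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  n <- length(rnodes)
  ids <- sub("^R_", "", xattr(rnodes, "id"))
  lbs <- ubs <- numeric(n)
  gprs <- subsys <- kinds <- character(n)
  confs <- integer(n)
  stoich <- vector("list", n)
  warned_bounds <- FALSE
  for (i in seq_len(n)) {
    node <- rnodes[[i]]
    kv <- notes_kv(node)
    subsys[i] <- kv$SUBSYSTEM %||% ""
    confs[i] <- suppressWarnings(as.integer(kv$CONFIDENCE %||% NA))
    kinds[i] <- kv$KIND %||% NA_character_
    lbp <- xattr(node, "fbc:lowerFluxBound", ns)
    ubp <- xattr(node, "fbc:upperFluxBound", ns)
    if (is.na(lbp) || is.na(ubp)) {
      warned_bounds <- TRUE
      rev <- identical(xattr(node, "reversible"), "true")
      lbs[i] <- if (rev) DEFAULT_LB else 0
      ubs[i] <- DEFAULT_UB
    } else {
      lbs[i] <- parval[[lbp]]
      ubs[i] <- parval[[ubp]]
    }
    st <- numeric(0)
    acc <- function(mid, coef) {
      cur <- if (mid %in% names(st)) st[[mid]] else 0
      st[mid] <<- cur + coef
    }
    for (sr in xml2::xml_find_all(node, "./s:listOfReactants/s:speciesReference", ns))
      acc(sid_to_met[[xattr(sr, "species")]],
          -as.numeric(xattr(sr, "stoichiometry")))
    for (sr in xml2::xml_find_all(node, "./s:listOfProducts/s:speciesReference", ns))
      acc(sid_to_met[[xattr(sr, "species")]],
          as.numeric(xattr(sr, "stoichiometry")))
    stoich[[i]] <- st
    gpa <- xml2::xml_find_first(node, "./fbc:geneProductAssociation", ns)
    gprs[i] <- if (inherits(gpa, "xml_missing")) "" else
      gpr_string(gpa_tree(xml2::xml_child(gpa)))
  }
  if (warned_bounds)
    warning("SBML reactions without flux bounds; defaults applied")
  names(stoich) <- ids

  objs <- xml2::xml_find_all(doc, ".//fbc:listOfObjectives/fbc:objective", ns)
  objectives <- character(0)
  for (o in objs) {
    fo <- xml2::xml_find_first(o, ".//fbc:fluxObjective", ns)
    objectives[xattr(o, "fbc:id", ns)] <- sub("^R_", "",
                                               xattr(fo, "fbc:reaction", ns))
  }
  rxns <- data.frame(id = ids, name = xattr(rnodes, "name"), lb = lbs, ub = ubs,
                     gpr = gprs, subsystem = subsys, confidence = confs,
                     stringsAsFactors = FALSE)
  if (!all(is.na(kinds))) rxns$kind <- kinds
  model <- metabolic_model(mets, rxns, stoich,
    genes = unname(gid_to_gene), objectives = objectives,
    ngam_reaction = if (nzchar(mkv$NGAM_REACTION %||% "")) mkv$NGAM_REACTION
                    else NA_character_,
    ngam_aerobic = as.numeric(mkv$NGAM_AEROBIC %||% 0.92),
    ngam_anaerobic = as.numeric(mkv$NGAM_ANAEROBIC %||% 0.15))
  if (!quiet)
    message("loaded model: ", nrow(model$reactions), " reactions, ",
            nrow(model$metabolites), " metabolites, ",
            length(model$genes), " genes")
  model
}

## ---- media -----------------------------------------------------------------

#' Define an in-silico medium
#'
#' A medium is a map of exchange-reaction bounds (mmol/gDW/h; negative lower
#' bound = permitted uptake). Exchanges not named keep uptake closed (lb = 0)
#' and secretion open. An anaerobic medium forces the O2 exchange closed.
#'
#' @param name medium name.
#' @param bounds named list, `exchange_id = c(lb, ub)`.
#' @param aerobic logical; `FALSE` pins the O2 exchange uptake to 0 and
#'   selects the anaerobic NGAM value.
#' @param o2_exchange id of the O2 exchange reaction (for the anaerobic
#'   closure).
#' @param ngam optional NGAM override (mmol/gDW/h); default: the model's
#'   aerobic or anaerobic value depending on `aerobic`.
#' @return object of class `medium_spec`.
#' @export
medium <- function(name, bounds, aerobic = TRUE, o2_exchange = "EX_o2_e",
                   ngam = NULL) {
  bounds <- lapply(bounds, function(b) {
    if (length(b) == 1) b <- c(b, DEFAULT_UB)
    stopifnot(length(b) == 2, b[1] <= b[2])
    as.numeric(b)
  })
  if (!aerobic) bounds[[o2_exchange]] <- c(0, bounds[[o2_exchange]][2] %||% DEFAULT_UB)
  structure(list(name = name, bounds = bounds, aerobic = aerobic,
                 o2_exchange = o2_exchange, ngam = ngam),
            class = "medium_spec")
}

#' @export
print.medium_spec <- function(x, ...) {
  cat("Medium", x$name, if (x$aerobic) "(aerobic)" else "(anaerobic)", "\n")
  for (nm in names(x$bounds))
    cat(sprintf("  %-16s [%g, %g]\n", nm, x$bounds[[nm]][1], x$bounds[[nm]][2]))
  invisible(x)
}

#' Read / write a medium definition (YAML or JSON)
#'
#' The file carries `name`, `aerobic`, optional `ngam` and `o2_exchange`, and
#' a `bounds` map of two-element `[lb, ub]` arrays keyed by exchange id.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return [medium()] object.
#' @export
read_medium <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  medium(cfg$name %||% "medium",
         bounds = lapply(cfg$bounds, as.numeric),
         aerobic = isTRUE(cfg$aerobic %||% TRUE),
         o2_exchange = cfg$o2_exchange %||% "EX_o2_e",
         ngam = cfg$ngam)
}

#' @rdname read_medium
#' @param med a `medium_spec`.
#' @export
write_medium <- function(med, path) {
  obj <- list(name = med$name, aerobic = med$aerobic,
              o2_exchange = med$o2_exchange,
              bounds = lapply(med$bounds, as.numeric))
  if (!is.null(med$ngam)) obj$ngam <- med$ngam
  if (grepl("\\.json$", path)) jsonlite::write_json(obj, path, auto_unbox = TRUE)
  else yaml::write_yaml(obj, path)
  invisible(path)
}

## ---- expression profiles ---------------------------------------------------

#' Construct an expression profile
#'
#' @param condition condition name.
#' @param fpkm named non-negative numeric vector of FPKM values keyed by gene
#'   id. Genes absent from the vector carry no data (they are not zero).
#' @return object of class `expression_profile`.
#' @export
expression_profile <- function(condition, fpkm) {
  stopifnot(!is.null(names(fpkm)), all(fpkm >= 0))
  structure(list(condition = condition, fpkm = fpkm),
            class = "expression_profile")
}

#' Read / write an expression table (TSV: gene_id, fpkm)
#' @param path TSV path.
#' @param condition condition name (default: file name without extension).
#' @return [expression_profile()].
#' @export
read_expression <- function(path, condition = NULL) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "fpkm") %in% names(tb)))
    stop("expression table needs columns gene_id, fpkm")
  expression_profile(condition %||% sub("\\.[^.]*$", "", basename(path)),
                     stats::setNames(as.numeric(tb$fpkm), tb$gene_id))
}

#' @rdname read_expression
#' @param profile an `expression_profile`.
#' @export
write_expression <- function(profile, path) {
  utils::write.table(
    data.frame(gene_id = names(profile$fpkm), fpkm = unname(profile$fpkm)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- ortholog hit tables ---------------------------------------------------

#' Read a BLAST outfmt-6-like hit table
#'
#' Expected tab-separated columns (with header): `qseqid`, `sseqid`, `pident`,
#' `qcovs`, `scovs`, `evalue`, optionally `bitscore`.
#'
#' @param path TSV path.
#' @return data.frame of hits.
#' @export
read_hits <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "pident", "qcovs", "scovs", "evalue")
  miss <- setdiff(need, names(tb))
  if (length(miss)) stop("hit table lacks columns: ", paste(miss, collapse = ", "))
  tb
}
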