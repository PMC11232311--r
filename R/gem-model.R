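## Compartmentalized genome-scale metabolic model (GEM) container and I/O.
##
## Metabolite ids carry the compartment as a bracket suffix ("glutamate[c]"),
## which is authoritative: the same chemical species in two compartments is
## two distinct metabolites. Reactions store signed stoichiometry (negative =
## substrate), reversibility, flux bounds and a boolean gene rule.

GEM_COMPARTMENTS <- c(c = "cytosol", m = "mitochondria", l = "lysosome",
                      r = "endoplasmic reticulum", g = "Golgi",
                      p = "peroxisome", n = "nucleus", s = "extracellular",
                      b = "boundary")

#' Construct a metabolic model
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `is_currency` (logical) and optionally `category`. The `id` must end in
#'   a `[x]` compartment bracket consistent with `compartment`.
#' @param reactions data.frame with columns `id`, `gene_rule`, `subsystem`,
#'   `lb`, `ub`, `reversible`.
#' @param stoichiometry Named list (by reaction id) of named numeric vectors
#'   (by metabolite id); negative coefficients are substrates.
#' @return An object of class `metabolic_model` with elements `metabolites`,
#'   `reactions`, `stoichiometry`, `genes` (union of gene ids in rules) and
#'   `compartments`.
#' @export
metabolic_model <- function(metabolites, reactions, stoichiometry) {
  metabolites <- as.data.frame(metabolites, stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  if (!"category" %in% names(metabolites)) metabolites$category <- NA_character_
  if (!"is_currency" %in% names(metabolites)) metabolites$is_currency <- FALSE
  if (!"name" %in% names(metabolites)) metabolites$name <- strip_compartment(metabolites$id)
  if (nrow(reactions) > 0) {
    if (!"subsystem" %in% names(reactions)) reactions$subsystem <- NA_character_
    if (!"gene_rule" %in% names(reactions)) reactions$gene_rule <- ""
    reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
    if (!"lb" %in% names(reactions)) reactions$lb <- ifelse(reactions$reversible, -1000, 0)
    if (!"ub" %in% names(reactions)) reactions$ub <- 1000
  } else {
    reactions <- data.frame(id = character(0), gene_rule = character(0),
                            subsystem = character(0), lb = numeric(0),
                            ub = numeric(0), reversible = logical(0),
                            stringsAsFactors = FALSE)
  }
  genes <- sort(unique(unlist(lapply(reactions$gene_rule, rule_genes))))
  model <- structure(
    list(metabolites = metabolites,
         reactions = reactions,
         stoichiometry = stoichiometry[reactions$id],
         genes = as.character(genes),
         compartments = sort(unique(metabolites$compartment))),
    class = "metabolic_model")
  validate_model(model)
  model
}

#' Validate a metabolic model
#'
#' Checks id uniqueness, compartment consistency between the `[x]` bracket
#' and the `compartment` column, dangling stoichiometry references,
#' empty-stoichiometry reactions, gene-rule parsability and the
#' irreversibility/bound contract (irreversible implies `lb >= 0`).
#'
#' @param model A `metabolic_model`.
#' @return `model`, invisibly; stops with an informative error otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite ids: ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxns$id[duplicated(rxns$id)]), collapse = ", "), call. = FALSE)
  }
  if (nrow(mets) > 0) {
    comp_from_id <- compartment_of(mets$id)
    bad <- which(is.na(comp_from_id) | comp_from_id != mets$compartment)
    if (length(bad)) {
      stop("metabolite id/compartment mismatch: ",
           paste(mets$id[bad], collapse = ", "), call. = FALSE)
    }
    unknown <- setdiff(mets$compartment, names(GEM_COMPARTMENTS))
    if (length(unknown)) {
      stop("unknown compartment code(s): ", paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  for (rid in rxns$id) {
    st <- model$stoichiometry[[rid]]
    if (is.null(st) || length(st) == 0 || all(st == 0)) {
      stop(sprintf("reaction '%s' has no nonzero stoichiometry", rid), call. = FALSE)
    }
    dangling <- setdiff(names(st), mets$id)
    if (length(dangling)) {
      stop(sprintf("reaction '%s' references unknown metabolite(s): %s",
                   rid, paste(dangling, collapse = ", ")), call. = FALSE)
    }
  }
  if (nrow(rxns) > 0) {
    lapply(rxns$gene_rule, parse_gene_rule)  # errors if unparsable
    bad_bounds <- which(!rxns$reversible & rxns$lb < 0)
    if (length(bad_bounds)) {
      stop("irreversible reaction(s) with negative lower bound: ",
           paste(rxns$id[bad_bounds], collapse = ", "), call. = FALSE)
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions, %d genes, %d compartments\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes),
              length(x$compartments)))
  invisible(x)
}

#' Compartment code encoded in a metabolite id
#'
#' @param id Metabolite id(s) with bracket suffix, e.g. `"glutamate[c]"`.
#' @return One-letter compartment code(s); `NA` when no bracket is present.
#' @export
compartment_of <- function(id) {
  m <- regmatches(id, regexpr("\\[([A-Za-z])\\]$", id))
  out <- rep(NA_character_, length(id))
  has <- grepl("\\[([A-Za-z])\\]$", id)
  out[has] <- sub("^.*\\[([A-Za-z])\\]$", "\\1", id[has])
  out
}

#' Metabolite id without its compartment bracket
#' @param id Metabolite id(s).
#' @return Character vector of bare names.
#' @export
strip_compartment <- function(id) {
  sub("\\[[A-Za-z]\\]$", "", id)
}

## ---- reaction equation strings (HMR arrow dialect) -------------------------

ARROW_IRREV <- c("⇒", "=>", "->")
ARROW_REV <- c("⇔", "<=>", "<->")

parse_equation_side <- function(side, rid, sign) {
  side <- trimws(side)
  if (!nzchar(side)) return(numeric(0))
  terms <- strsplit(side, "\\s+\\+\\s+")[[1]]
  coef <- numeric(0)
  for (term in terms) {
    term <- trimws(term)
    m <- regexec("^([0-9]*\\.?[0-9]+\\s+)?(.+)$", term)[[1]]
    parts <- regmatches(term, list(m))[[1]]
    k <- if (nzchar(trimws(parts[2]))) as.numeric(trimws(parts[2])) else 1
    met <- trimws(parts[3])
    if (!nzchar(met) || is.na(compartment_of(met))) {
      stop(sprintf("reaction '%s': malformed stoichiometry term '%s'", rid, term),
           call. = FALSE)
    }
    prev <- if (met %in% names(coef)) coef[[met]] else 0
    coef[met] <- prev + sign * k
  }
  coef
}

#' Parse an HMR-style reaction equation
#'
#' Accepts the unicode arrows `⇒` (irreversible) and `⇔`
#' (reversible) as printed in HMR reaction strings, plus the ASCII forms
#' `=>`/`->` and `<=>`/`<->`. Either side may be empty (exchange/boundary
#' reactions). Coefficients precede metabolite ids, e.g.
#' `"2 H2O[c] + ATP[c] ⇒ ADP[c] + Pi[c]"`.
#'
#' @param equation Equation string.
#' @param rid Reaction id used in error messages.
#' @return List with `stoich` (named numeric, negative = substrate) and
#'   `reversible` (logical).
#' @export
parse_reaction_equation <- function(equation, rid = "?") {
  equation <- trimws(equation)
  arrow <- NULL
  reversible <- NA
  for (a in ARROW_REV) {
    if (grepl(a, equation, fixed = TRUE)) { arrow <- a; reversible <- TRUE; break }
  }
  if (is.null(arrow)) {
    for (a in ARROW_IRREV) {
      if (grepl(a, equation, fixed = TRUE)) { arrow <- a; reversible <- FALSE; break }
    }
  }
  if (is.null(arrow)) {
    stop(sprintf("reaction '%s': no reaction arrow found in '%s'", rid, equation),
         call. = FALSE)
  }
  sides <- strsplit(equation, arrow, fixed = TRUE)[[1]]
  if (length(sides) == 1L) sides <- c(sides, "")
  if (length(sides) != 2L) {
    stop(sprintf("reaction '%s': more than one arrow in '%s'", rid, equation),
         call. = FALSE)
  }
  lhs <- parse_equation_side(sides[1], rid, -1)
  rhs <- parse_equation_side(sides[2], rid, +1)
  stoich <- lhs
  for (met in names(rhs)) {
    stoich[met] <- (if (met %in% names(stoich)) stoich[[met]] else 0) + rhs[[met]]
  }
  stoich <- stoich[stoich != 0]
  if (length(stoich) == 0) {
    stop(sprintf("reaction '%s': empty or self-cancelling stoichiometry", rid),
         call. = FALSE)
  }
  list(stoich = stoich, reversible = reversible)
}

#' Format a stoichiometry vector as an equation string
#'
#' Inverse of [parse_reaction_equation()], using the unicode HMR arrows.
#'
#' @param stoich Named numeric stoichiometry (negative = substrate).
#' @param reversible Logical.
#' @return Equation string.
#' @export
format_reaction_equation <- function(stoich, reversible) {
  fmt_side <- function(v) {
    if (length(v) == 0) return("")
    paste(vapply(names(v), function(met) {
      k <- v[[met]]
      if (k == 1) met else paste(format(k, trim = TRUE), met)
    }, character(1)), collapse = " + ")
  }
  lhs <- -stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  arrow <- if (reversible) "⇔" else "⇒"
  trimws(paste(fmt_side(lhs), arrow, fmt_side(rhs)))
}

## ---- tabular dialect -------------------------------------------------------

#' Read a metabolic model
#'
#' The tabular dialect is a directory holding `metabolites.tsv`
#' (`id`, `name`, `compartment`, `is_currency`, `category`) and
#' `reactions.tsv` (`id`, `equation`, `gene_rule`, `subsystem`, `lb`, `ub`)
#' with HMR arrow notation in `equation`. `format = "sbml"` reads a single
#' SBML Level 3 file written by [write_model()].
#'
#' @param path Directory (tabular) or file (sbml).
#' @param format `"tabular"` or `"sbml"`.
#' @return A validated `metabolic_model`.
#' @export
read_model <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "sbml") return(read_model_sbml(path))
  met_path <- file.path(path, "metabolites.tsv")
  rxn_path <- file.path(path, "reactions.tsv")
  for (p in c(met_path, rxn_path)) {
    if (!file.exists(p)) stop("model file not found: ", p, call. = FALSE)
  }
  mets <- read_tsv_table(met_path)
  rxns <- read_tsv_table(rxn_path)
  mets$is_currency <- as.logical(mets$is_currency)
  if (!"category" %in% names(mets)) mets$category <- NA_character_
  stoich <- list()
  reversible <- logical(nrow(rxns))
  if (nrow(rxns) > 0) {
    for (i in seq_len(nrow(rxns))) {
      parsed <- tryCatch(parse_reaction_equation(rxns$equation[i], rxns$id[i]),
                         error = function(e) {
                           stop(sprintf("reactions.tsv record %d: %s", i,
                                        conditionMessage(e)), call. = FALSE)
                         })
      stoich[[rxns$id[i]]] <- parsed$stoich
      reversible[i] <- parsed$reversible
    }
  }
  reactions <- data.frame(id = as.character(rxns$id %||% character(0)),
                          gene_rule = if (nrow(rxns)) ifelse(is.na(rxns$gene_rule), "", rxns$gene_rule) else character(0),
                          subsystem = if ("subsystem" %in% names(rxns) && nrow(rxns)) rxns$subsystem else rep(NA_character_, nrow(rxns)),
                          lb = if (nrow(rxns)) as.numeric(rxns$lb) else numeric(0),
                          ub = if (nrow(rxns)) as.numeric(rxns$ub) else numeric(0),
                          reversible = reversible,
                          stringsAsFactors = FALSE)
  metabolic_model(mets, reactions, stoich)
}

#' Write a metabolic model
#'
#' @param model A `metabolic_model`.
#' @param path Output directory (tabular) or file (sbml); created if needed.
#' @param format `"tabular"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "sbml") return(write_model_sbml(model, path))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_tsv_table(model$metabolites[, c("id", "name", "compartment", "is_currency", "category")],
                  file.path(path, "metabolites.tsv"))
  rxns <- model$reactions
  eq <- vapply(rxns$id, function(rid) {
    format_reaction_equation(model$stoichiometry[[rid]], rxns$reversible[rxns$id == rid])
  }, character(1))
  out <- data.frame(id = rxns$id, equation = unname(eq), gene_rule = rxns$gene_rule,
                    subsystem = rxns$subsystem, lb = rxns$lb, ub = rxns$ub,
                    stringsAsFactors = FALSE)
  write_tsv_table(out, file.path(path, "reactions.tsv"))
  invisible(path)
}

#' Stoichiometric matrix of a model
#'
#' @param model A `metabolic_model`.
#' @param sparse Return a `Matrix::sparseMatrix` (default) or dense matrix.
#' @return Metabolites x reactions matrix of signed coefficients, with
#'   dimnames.
#' @export
stoichiometric_matrix <- function(model, sparse = TRUE) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (jj in seq_along(rxn_ids)) {
    st <- model$stoichiometry[[rxn_ids[jj]]]
    i <- c(i, match(names(st), met_ids))
    j <- c(j, rep(jj, length(st)))
    x <- c(x, unname(st))
  }
  S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  if (sparse) S else as.matrix(S)
}

#' Extract a sub-model restricted to a reaction set
#'
#' Keeps the given reactions and every metabolite participating in at least
#' one of them.
#'
#' @param model A `metabolic_model`.
#' @param reaction_ids Reaction ids to keep.
#' @return A `metabolic_model`.
#' @export
subset_model <- function(model, reaction_ids) {
  reaction_ids <- intersect(model$reactions$id, reaction_ids)
  rxns <- model$reactions[model$reactions$id %in% reaction_ids, , drop = FALSE]
  st <- model$stoichiometry[reaction_ids]
  used_mets <- unique(unlist(lapply(st, names)))
  mets <- model$metabolites[model$metabolites$id %in% used_mets, , drop = FALSE]
  rownames(mets) <- NULL
  rownames(rxns) <- NULL
  metabolic_model(mets, rxns, st)
}

## ---- minimal SBML L3 read/write -------------------------------------------

sbml_mangle <- function(id) {
  paste0("M_", gsub("[^A-Za-z0-9_]", "_", strip_compartment(id)), "_", compartment_of(id))
}

write_model_sbml <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "gem")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (comp in model$compartments) {
    xml2::xml_add_child(lc, "compartment", id = comp, constant = "true",
                        name = unname(GEM_COMPARTMENTS[comp]))
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  mets <- model$metabolites
  sid <- sbml_mangle(mets$id)
  for (i in seq_len(nrow(mets))) {
    xml2::xml_add_child(ls, "species", id = sid[i], name = mets$name[i],
                        compartment = mets$compartment[i],
                        constant = "false", boundaryCondition = "false",
                        hasOnlySubstanceUnits = "false",
                        metaid = mets$id[i],
                        gemIsCurrency = tolower(as.character(mets$is_currency[i])),
                        gemCategory = ifelse(is.na(mets$category[i]), "", mets$category[i]))
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(lr, "reaction", id = gsub("[^A-Za-z0-9_]", "_", r$id),
                              metaid = r$id,
                              reversible = tolower(as.character(r$reversible)),
                              fast = "false",
                              gemLb = format(r$lb), gemUb = format(r$ub),
                              gemGeneRule = r$gene_rule,
                              gemSubsystem = ifelse(is.na(r$subsystem), "", r$subsystem))
    st <- model$stoichiometry[[r$id]]
    reac <- xml2::xml_add_child(rn, "listOfReactants")
    prod <- xml2::xml_add_child(rn, "listOfProducts")
    for (met in names(st)) {
      k <- st[[met]]
      parent <- if (k < 0) reac else prod
      xml2::xml_add_child(parent, "speciesReference",
                          species = sbml_mangle(met), metaid = met,
                          stoichiometry = format(abs(k)), constant = "true")
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = xml2::xml_attr(sp, "metaid"),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    is_currency = xml2::xml_attr(sp, "gemIsCurrency") == "true",
    category = xml2::xml_attr(sp, "gemCategory"),
    stringsAsFactors = FALSE)
  mets$category[!nzchar(mets$category) | is.na(mets$category)] <- NA_character_
  rx <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  stoich <- list()
  reactions <- data.frame(
    id = xml2::xml_attr(rx, "metaid"),
    gene_rule = xml2::xml_attr(rx, "gemGeneRule"),
    subsystem = xml2::xml_attr(rx, "gemSubsystem"),
    lb = as.numeric(xml2::xml_attr(rx, "gemLb")),
    ub = as.numeric(xml2::xml_attr(rx, "gemUb")),
    reversible = xml2::xml_attr(rx, "reversible") == "true",
    stringsAsFactors = FALSE)
  reactions$subsystem[!nzchar(reactions$subsystem) | is.na(reactions$subsystem)] <- NA_character_
  reactions$gene_rule[is.na(reactions$gene_rule)] <- ""
  for (i in seq_along(rx)) {
    reac <- xml2::xml_find_all(rx[[i]], "./listOfReactants/speciesReference")
    prod <- xml2::xml_find_all(rx[[i]], "./listOfProducts/speciesReference")
    st <- c(
      stats::setNames(-as.numeric(xml2::xml_attr(reac, "stoichiometry")),
                      xml2::xml_attr(reac, "metaid")),
      stats::setNames(as.numeric(xml2::xml_attr(prod, "stoichiometry")),
                      xml2::xml_attr(prod, "metaid")))
    stoich[[reactions$id[i]]] <- st
  }
  metabolic_model(mets, reactions, stoich)
}
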