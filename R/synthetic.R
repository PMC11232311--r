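## Synthetic data generator.
##
## Emulates the statistical structure the pipeline assumes: a
## compartmentalized toy GEM with a planted high-connectivity hub
## metabolite bridging cytosol and mitochondria (wired around the
## glutamate/glutamine reaction triplet), currency metabolites, two-cohort
## log-scale expression with planted up-regulation of hub-adjacent enzyme
## genes in the case group, and batch-structured metabolomics with pooled
## QC samples, missingness and planted abundance shifts.

#' Define a synthetic scenario
#'
#' Defaults mirror the study design the pipeline targets: a case/control
#' contrast (hemorrhaged vs non-hemorrhaged plaque), a primary cohort of
#' 16 + 27 samples and a larger 126-sample support cohort, hub-adjacent
#' genes shifted by two noise standard deviations, and metabolomics in
#' three batches with 35 primary (9 control, 26 case) and 11 pooled-QC
#' samples.
#'
#' @param seed Integer master seed recorded in every derived artifact.
#' @param n_pathways Number of background linear pathways (default 10).
#' @param pathway_size Range of pathway lengths (default `c(3, 6)`).
#' @param hub_degree Number of reactions incident to the planted hub
#'   metabolite `glutamate[c]` (default 8; must exceed twice the background
#'   median metabolite degree).
#' @param delta Planted log2 expression shift of hub-adjacent genes in the
#'   case group (default 1).
#' @param sigma Expression noise SD on the log2 scale (default 0.5, so the
#'   default shift is 2 sigma).
#' @param affected_frac Fraction of hub-adjacent genes shifted (default 1).
#' @param n_control,n_case Primary-cohort group sizes (defaults 16 and 27).
#' @param n_support Support-cohort size (default 126).
#' @param n_background_genes Non-metabolic genes padding the expression
#'   matrix so quartile tiers are populated (default 150).
#' @param met_batches Number of metabolomics batches (default 3).
#' @param met_n_control,met_n_case Primary metabolomics samples per group
#'   (defaults 9 and 26).
#' @param met_n_qc Pooled-QC injections (default 11).
#' @param met_missing_rate Completely-at-random missingness (default 0.05).
#' @param met_n_total Total metabolite panel size (default 109).
#' @param met_shift_fold Fold change of planted metabolomics shifts
#'   (default 1.8; the hub metabolite itself is planted down at 1/1.8).
#' @return A `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(seed = 1L,
                               n_pathways = 10,
                               pathway_size = c(3, 6),
                               hub_degree = 8,
                               delta = 1,
                               sigma = 0.5,
                               affected_frac = 1,
                               n_control = 16, n_case = 27,
                               n_support = 126,
                               n_background_genes = 150,
                               met_batches = 3,
                               met_n_control = 9, met_n_case = 26,
                               met_n_qc = 11,
                               met_missing_rate = 0.05,
                               met_n_total = 109,
                               met_shift_fold = 1.8) {
  structure(list(seed = as.integer(seed), n_pathways = n_pathways,
                 pathway_size = pathway_size, hub_degree = hub_degree,
                 delta = delta, sigma = sigma, affected_frac = affected_frac,
                 n_control = n_control, n_case = n_case,
                 n_support = n_support,
                 n_background_genes = n_background_genes,
                 met_batches = met_batches,
                 met_n_control = met_n_control, met_n_case = met_n_case,
                 met_n_qc = met_n_qc, met_missing_rate = met_missing_rate,
                 met_n_total = met_n_total, met_shift_fold = met_shift_fold),
            class = "synthetic_scenario")
}

#' Generate the toy metabolic model of a scenario
#'
#' The model spans cytosol, mitochondria and the extracellular space, holds
#' the glutamate/glutamine fixture reactions (amidation of glutamate to
#' glutamine, hydrolysis back, and the aspartate/glutamate carrier between
#' cytosol and mitochondria), currency metabolites flagged as such, linear
#' background pathways with 1-3 genes per reaction, exchange reactions
#' keeping every pathway flux-consistent, and extra reactions wiring the
#' hub metabolite `glutamate[c]` up to `hub_degree` incident reactions.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A validated, flux-consistent `metabolic_model`; the planted
#'   truth is in `attr(, "truth")` (`hub`, `hub_genes`).
#' @export
generate_toy_model <- function(scenario = synthetic_scenario()) {
  with_seed(scenario$seed + 101L, {
    mets <- list(); rxns <- list(); stoich <- list()
    add_met <- function(id, name = strip_compartment(id), currency = FALSE,
                        category = NA_character_) {
      if (!id %in% names(mets)) {
        mets[[id]] <<- data.frame(id = id, name = name,
                                  compartment = compartment_of(id),
                                  is_currency = currency, category = category,
                                  stringsAsFactors = FALSE)
      }
    }
    add_rxn <- function(id, equation, gene_rule = "", subsystem = NA_character_,
                        lb = NULL, ub = 1000) {
      parsed <- parse_reaction_equation(equation, id)
      for (met in names(parsed$stoich)) add_met(met)
      if (is.null(lb)) lb <- if (parsed$reversible) -1000 else 0
      rxns[[id]] <<- data.frame(id = id, gene_rule = gene_rule,
                                subsystem = subsystem, lb = lb, ub = ub,
                                reversible = parsed$reversible,
                                stringsAsFactors = FALSE)
      stoich[[id]] <<- parsed$stoich
    }

    ## currency metabolites (flagged; removed later by build_graph)
    for (id in c("ATP[c]", "ADP[c]", "Pi[c]", "H2O[c]", "H+[c]", "H+[m]")) {
      add_met(id, currency = TRUE)
    }

    ## glutamate/glutamine fixture triplet with its enzyme genes
    add_met("glutamate[c]", "glutamate", category = "amino acid")
    add_met("glutamine[c]", "glutamine", category = "amino acid")
    add_met("glutamate[m]", "glutamate", category = "amino acid")
    add_met("aspartate[c]", "aspartate", category = "amino acid")
    add_met("aspartate[m]", "aspartate", category = "amino acid")
    add_met("NH3[c]", "NH3")
    add_rxn("HMR_3890", "ATP[c] + NH3[c] + glutamate[c] ⇒ ADP[c] + Pi[c] + glutamine[c]",
            "GLUL", "glutamate metabolism")
    add_rxn("HMR_9802", "H2O[c] + glutamine[c] ⇒ NH3[c] + glutamate[c]",
            "GLS", "glutamate metabolism")
    add_rxn("HMR_3825", "H+[c] + aspartate[m] + glutamate[c] ⇒ H+[m] + aspartate[c] + glutamate[m]",
            "SLC25A12 or SLC25A13", "amino acid transport")

    ## extra hub reactions: transaminase-style partners in cytosol and the
    ## mitochondrial bridge, each with its own gene
    hub_extra_genes <- c("GOT1", "GPT2", "GLUD1", "ASNS", "ALDH18A1",
                         "ABAT", "GFPT1", "PFAS")
    n_extra <- max(0, scenario$hub_degree - 3)
    for (i in seq_len(n_extra)) {
      gene <- hub_extra_genes[((i - 1) %% length(hub_extra_genes)) + 1]
      comp <- if (i %% 2 == 0) "m" else "c"
      partner <- sprintf("hubpartner%d[%s]", i, comp)
      prod <- sprintf("hubproduct%d[c]", i)
      add_met(partner); add_met(prod)
      if (comp == "m") {
        add_rxn(sprintf("HUB_%02d", i),
                sprintf("glutamate[c] + %s ⇔ %s + glutamate[m]", partner, prod),
                gene, "glutamate metabolism")
      } else {
        add_rxn(sprintf("HUB_%02d", i),
                sprintf("glutamate[c] + %s ⇔ %s", partner, prod),
                gene, "glutamate metabolism")
      }
      add_rxn(sprintf("EX_hubpartner%d", i), sprintf("%s ⇔", partner))
      add_rxn(sprintf("EX_hubproduct%d", i), sprintf("%s ⇔", prod))
    }

    ## exchanges making the glutamate module consistent
    for (id in c("glutamate[c]", "glutamine[c]", "NH3[c]", "aspartate[m]",
                 "aspartate[c]", "glutamate[m]", "ATP[c]", "ADP[c]", "Pi[c]",
                 "H2O[c]", "H+[c]", "H+[m]")) {
      add_rxn(paste0("EX_", gsub("[^A-Za-z0-9]", "_", id)), paste(id, "⇔"))
    }

    ## background linear pathways
    categories <- c("sugar", "sphingolipid", "glycerophospholipid",
                    "cholesterol derivative", "organic acid")
    for (p in seq_len(scenario$n_pathways)) {
      len <- sample(seq(scenario$pathway_size[1], scenario$pathway_size[2]), 1)
      comp <- sample(c("c", "m"), 1)
      cat_p <- categories[((p - 1) %% length(categories)) + 1]
      ids <- sprintf("pw%02dmet%d[%s]", p, seq_len(len), comp)
      ## substrate enters from the extracellular space via a transporter
      ext <- sprintf("pw%02dmet1[s]", p)
      add_met(ext, category = cat_p)
      for (id in ids) add_met(id, category = cat_p)
      add_rxn(sprintf("EX_pw%02d_in", p), paste("⇒", ext))
      add_rxn(sprintf("PW%02d_T0", p), sprintf("%s ⇒ %s", ext, ids[1]),
              sprintf("PW%02dG0_1", p), paste(cat_p, "transport"))
      for (j in seq_len(len - 1)) {
        n_genes <- sample(1:3, 1)
        genes <- sprintf("PW%02dG%d_%d", p, j, seq_len(n_genes))
        rule <- paste(genes, collapse = " or ")
        add_rxn(sprintf("PW%02d_R%d", p, j),
                sprintf("%s ⇒ %s", ids[j], ids[j + 1]), rule,
                paste(cat_p, "pathway"))
      }
      add_rxn(sprintf("EX_pw%02d_out", p), paste(ids[len], "⇒"))
    }

    met_df <- do.call(rbind, mets)
    rxn_df <- do.call(rbind, rxns)
    rownames(met_df) <- rownames(rxn_df) <- NULL
    model <- metabolic_model(met_df, rxn_df, stoich)

    hub_genes <- neighbor_genes(model, "glutamate[c]")
    attr(model, "truth") <- list(hub = "glutamate[c]", hub_genes = hub_genes,
                                 seed = scenario$seed)
    model
  })
}

#' Generate two-cohort expression matrices and a DEG table
#'
#' Per-gene log2 baselines are spread so every quartile tier is populated;
#' values are Gaussian around the baseline with SD `sigma`. A fraction
#' `affected_frac` of the hub-adjacent genes is shifted by `delta` in the
#' case group of both cohorts. The DEG table comes from per-gene two-sample
#' t-tests on the primary cohort with BH adjustment (a generator-internal
#' convenience; real studies would use a dedicated microarray pipeline).
#'
#' @param model Toy model from [generate_toy_model()].
#' @param scenario A `synthetic_scenario`.
#' @return List with `primary` (matrix), `primary_groups` (factor),
#'   `support` (matrix), `deg` (data.frame `gene`, `log2fc`, `p`, `p_adj`)
#'   and `truth` (planted gene set, delta, seed).
#' @export
generate_expression <- function(model, scenario = synthetic_scenario()) {
  truth <- attr(model, "truth")
  hub_genes <- truth$hub_genes %||% neighbor_genes(model, "glutamate[c]")
  with_seed(scenario$seed + 202L, {
    genes <- c(model$genes,
               sprintf("BG%03d", seq_len(scenario$n_background_genes)))
    n_genes <- length(genes)
    baseline <- stats::runif(n_genes, 2, 12)
    names(baseline) <- genes
    ## keep the planted genes comfortably expressed
    baseline[hub_genes] <- stats::runif(length(hub_genes), 8, 11)
    n_aff <- max(1L, round(scenario$affected_frac * length(hub_genes)))
    planted <- sort(sample(hub_genes, n_aff))

    simulate_cohort <- function(n_ctrl, n_case, label) {
      n <- n_ctrl + n_case
      x <- matrix(stats::rnorm(n_genes * n, mean = baseline, sd = scenario$sigma),
                  nrow = n_genes, ncol = n)
      rownames(x) <- genes
      colnames(x) <- sprintf("%s_S%03d", label, seq_len(n))
      grp <- factor(rep(c("ctrl", "case"), c(n_ctrl, n_case)),
                    levels = c("ctrl", "case"))
      x[planted, grp == "case"] <- x[planted, grp == "case"] + scenario$delta
      list(x = x, groups = grp)
    }
    prim <- simulate_cohort(scenario$n_control, scenario$n_case, "MH")
    supp <- simulate_cohort(ceiling(scenario$n_support / 2),
                            floor(scenario$n_support / 2), "BK")

    grp <- prim$groups
    deg <- do.call(rbind, lapply(genes, function(g) {
      a <- prim$x[g, grp == "case"]; b <- prim$x[g, grp == "ctrl"]
      tt <- stats::t.test(a, b)
      data.frame(gene = g, log2fc = mean(a) - mean(b), p = tt$p.value,
                 stringsAsFactors = FALSE)
    }))
    deg$p_adj <- stats::p.adjust(deg$p, method = "BH")
    rownames(deg) <- NULL
    list(primary = prim$x, primary_groups = prim$groups,
         support = supp$x,
         deg = deg,
         truth = list(planted_genes = planted, delta = scenario$delta,
                      sigma = scenario$sigma, seed = scenario$seed))
  })
}

#' Generate a batch-structured metabolomics matrix
#'
#' Log-normal abundances with per-batch multiplicative factors; QC samples
#' are drawn around the pooled mean with tighter noise; planted shifts:
#' the hub metabolite (glutamate) is reduced in the case group and most of
#' the `sphingolipid` category is raised, so at least one category is
#' enriched for shifts. Missingness is injected completely at random.
#'
#' @param model Toy model from [generate_toy_model()].
#' @param scenario A `synthetic_scenario`.
#' @return List with `matrix` (a `metabolomics_matrix`), `categories`
#'   (data.frame `metabolite`, `category`) and `truth` (shifted
#'   metabolites with folds, batch factors, seed).
#' @export
generate_metabolomics <- function(model, scenario = synthetic_scenario()) {
  with_seed(scenario$seed + 303L, {
    model_mets <- model$metabolites[!model$metabolites$is_currency, , drop = FALSE]
    panel <- unique(data.frame(metabolite = model_mets$name,
                               category = model_mets$category,
                               stringsAsFactors = FALSE))
    panel$category[is.na(panel$category)] <- "other"
    extra_specs <- list(c("sphingolipid", 14), c("sugar", 10),
                        c("glycerophospholipid", 6),
                        c("cholesterol derivative", 4), c("amino acid", 8))
    for (spec in extra_specs) {
      nm <- sprintf("%s_%02d", gsub("[^a-z]", "", spec[1]), seq_len(as.integer(spec[2])))
      panel <- rbind(panel, data.frame(metabolite = nm, category = spec[1],
                                       stringsAsFactors = FALSE))
    }
    panel <- panel[!duplicated(panel$metabolite), , drop = FALSE]
    if (nrow(panel) < scenario$met_n_total) {
      nm <- sprintf("filler_%03d", seq_len(scenario$met_n_total - nrow(panel)))
      panel <- rbind(panel, data.frame(metabolite = nm, category = "other",
                                       stringsAsFactors = FALSE))
    }
    panel <- panel[seq_len(min(nrow(panel), scenario$met_n_total)), , drop = FALSE]
    mets <- panel$metabolite

    ## planted shifts: hub metabolite down; most sphingolipids up
    shift_fold <- stats::setNames(rep(1, length(mets)), mets)
    if ("glutamate" %in% mets) shift_fold[["glutamate"]] <- 1 / scenario$met_shift_fold
    sph <- panel$metabolite[panel$category == "sphingolipid"]
    n_sph_up <- ceiling(0.7 * length(sph))
    sph_up <- sort(sample(sph, n_sph_up))
    shift_fold[sph_up] <- scenario$met_shift_fold

    n_primary <- scenario$met_n_control + scenario$met_n_case
    n_samples <- n_primary + scenario$met_n_qc
    sample_ids <- c(sprintf("P%02d", seq_len(n_primary)),
                    sprintf("QC%02d", seq_len(scenario$met_n_qc)))
    group <- c(rep(c("IPH-", "IPH+"), c(scenario$met_n_control, scenario$met_n_case)),
               rep("none", scenario$met_n_qc))
    sample_type <- rep(c("primary", "QC"), c(n_primary, scenario$met_n_qc))
    batch <- sample(rep_len(sprintf("B%d", seq_len(scenario$met_batches)), n_samples))
    ## ensure every batch has at least one QC sample
    for (b in sprintf("B%d", seq_len(scenario$met_batches))) {
      if (!any(batch == b & sample_type == "QC")) {
        batch[which(sample_type == "QC")[1]] <- b
      }
    }
    batch_factor <- stats::setNames(exp(stats::rnorm(scenario$met_batches, 0, 0.3)),
                                    sprintf("B%d", seq_len(scenario$met_batches)))

    base <- stats::setNames(exp(stats::runif(length(mets), log(1e3), log(1e5))), mets)
    ab <- matrix(NA_real_, nrow = length(mets), ncol = n_samples,
                 dimnames = list(mets, sample_ids))
    for (j in seq_len(n_samples)) {
      bf <- batch_factor[[batch[j]]]
      if (sample_type[j] == "QC") {
        ab[, j] <- base * bf * exp(stats::rnorm(length(mets), 0, 0.10))
      } else {
        fold <- if (group[j] == "IPH+") shift_fold else rep(1, length(mets))
        ab[, j] <- base * fold * bf * exp(stats::rnorm(length(mets), 0, 0.30))
      }
    }
    ## MCAR missingness on primary samples only (QC pools are always detected)
    prim_cols <- which(sample_type == "primary")
    miss <- matrix(stats::runif(length(mets) * length(prim_cols)) < scenario$met_missing_rate,
                   nrow = length(mets))
    ab[, prim_cols][miss] <- NA_real_

    m <- metabolomics_matrix(ab, data.frame(sample = sample_ids, batch = batch,
                                            sample_type = sample_type,
                                            group = group,
                                            stringsAsFactors = FALSE))
    list(matrix = m,
         categories = panel,
         truth = list(shifted = shift_fold[shift_fold != 1],
                      enriched_category = "sphingolipid",
                      batch_factors = batch_factor,
                      seed = scenario$seed))
  })
}
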