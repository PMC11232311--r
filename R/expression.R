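## Expression-tier classification driving context-specific model extraction.
##
## Genes are binned into HIGH / MEDIUM / LOW / ABSENT tiers against the
## quartiles of the POOLED expression distribution of the whole matrix (all
## gene x sample values), the convention used for microarray noise
## filtering: a gene is ABSENT when it sits below the pooled lower quartile
## in more than `absent_sample_frac` of its samples; otherwise its tier is
## set by its maximum expression.

EXPRESSION_TIERS <- c("HIGH", "MEDIUM", "LOW", "ABSENT")

#' Default tier scores for reaction weighting
#'
#' Magnitudes are chosen so that a single HIGH gene cannot outweigh two
#' ABSENT genes in an OR rule aggregate.
#' @export
default_tier_scores <- c(HIGH = 5, MEDIUM = 1, LOW = -2, ABSENT = -8)

#' Classify genes into expression tiers
#'
#' @param expr Numeric matrix, genes x samples (log scale), with rownames.
#'   All values must be finite; duplicate gene ids are an error (collapse
#'   isoforms beforehand).
#' @param absent_sample_frac A gene is ABSENT when its value is strictly
#'   below the pooled lower quartile in strictly more than this fraction of
#'   its samples (default 0.80).
#' @param q_low,q_high Pooled quantiles delimiting the tiers (defaults 0.25
#'   and 0.75, type-7 estimator).
#' @param cohort Optional cohort label stored as an attribute.
#' @return data.frame with columns `gene`, `tier`, `provenance`
#'   (`"quartile"`); attributes `q1`, `q3`, `cohort`.
#' @export
classify_genes <- function(expr, absent_sample_frac = 0.80,
                           q_low = 0.25, q_high = 0.75, cohort = NA_character_) {
  expr <- as.matrix(expr)
  if (nrow(expr) == 0) stop("empty expression matrix", call. = FALSE)
  if (is.null(rownames(expr))) stop("expression matrix must have gene rownames", call. = FALSE)
  if (anyDuplicated(rownames(expr))) {
    stop("duplicate gene ids in expression matrix; collapse isoforms first", call. = FALSE)
  }
  if (!all(is.finite(expr))) stop("expression values must be finite", call. = FALSE)
  if (!(q_low > 0 && q_low < q_high && q_high < 1)) {
    stop("need 0 < q_low < q_high < 1", call. = FALSE)
  }
  qs <- stats::quantile(as.vector(expr), probs = c(q_low, q_high),
                        type = 7, names = FALSE)
  q1 <- qs[1]; q3 <- qs[2]
  if (q1 >= q3) {
    stop("degenerate expression matrix: pooled quartiles coincide", call. = FALSE)
  }
  frac_below <- rowMeans(expr < q1)
  maxed <- apply(expr, 1, max)
  tier <- ifelse(frac_below > absent_sample_frac, "ABSENT",
                 ifelse(maxed > q3, "HIGH",
                        ifelse(maxed > q1, "MEDIUM", "LOW")))
  out <- data.frame(gene = rownames(expr), tier = unname(tier),
                    provenance = "quartile", stringsAsFactors = FALSE)
  attr(out, "q1") <- q1
  attr(out, "q3") <- q3
  attr(out, "cohort") <- cohort
  out
}

#' Combine tier classifications from multiple cohorts
#'
#' Cohorts are never averaged; per gene the best (highest) tier across
#' cohorts wins, with HIGH > MEDIUM > LOW > ABSENT. Genes present in only
#' one cohort keep that cohort's tier.
#'
#' @param ... classification data.frames from [classify_genes()].
#' @return Combined classification data.frame.
#' @export
combine_classes <- function(...) {
  pieces <- list(...)
  stopifnot(length(pieces) >= 1)
  all_rows <- do.call(rbind, lapply(pieces, function(p) p[, c("gene", "tier", "provenance")]))
  ord <- match(all_rows$tier, EXPRESSION_TIERS)  # 1 = HIGH
  best <- tapply(seq_len(nrow(all_rows)), all_rows$gene, function(idx) idx[which.min(ord[idx])])
  out <- all_rows[unlist(best), , drop = FALSE]
  out <- out[order(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Force genes to the HIGH tier from external evidence
#'
#' Genes differentially expressed below `p_adj_force` and genes on the
#' detected-protein list are set to HIGH regardless of their quartile tier.
#' Forced genes absent from `classes` are added (they may be unexpressed in
#' the classified cohort yet evidenced elsewhere). Idempotent.
#'
#' @param classes Classification data.frame from [classify_genes()].
#' @param deg Differential-expression data.frame with columns `gene`,
#'   `log2fc`, `p`, `p_adj`; may be `NULL`.
#' @param p_adj_force Adjusted-p threshold for forced inclusion (default
#'   0.001; 0.01 is the other defensible choice for the same rule and is
#'   exposed here rather than hard-wired).
#' @param proteins Character vector of detected-protein gene ids; may be
#'   `NULL`.
#' @param quiet Suppress the message listing added genes.
#' @return Updated classification data.frame; forced rows carry provenance
#'   `"forced_deg"` or `"forced_protein"`.
#' @export
force_high <- function(classes, deg = NULL, p_adj_force = 0.001,
                       proteins = NULL, quiet = FALSE) {
  forced_deg <- character(0)
  if (!is.null(deg) && nrow(deg) > 0) {
    forced_deg <- deg$gene[deg$p_adj < p_adj_force]
  }
  forced_prot <- unique(as.character(proteins %||% character(0)))
  apply_force <- function(classes, genes, prov) {
    if (length(genes) == 0) return(classes)
    known <- genes %in% classes$gene
    idx <- match(genes[known], classes$gene)
    ## do not overwrite an earlier forced provenance with a later one
    classes$tier[idx] <- "HIGH"
    classes$provenance[idx] <- ifelse(grepl("^forced", classes$provenance[idx]),
                                      classes$provenance[idx], prov)
    new_genes <- setdiff(genes[!known], classes$gene)
    if (length(new_genes)) {
      if (!quiet) {
        message(sprintf("force_high: adding %d gene(s) not in the classified cohort (%s)",
                        length(new_genes), prov))
      }
      classes <- rbind(classes,
                       data.frame(gene = new_genes, tier = "HIGH",
                                  provenance = prov, stringsAsFactors = FALSE))
    }
    classes
  }
  atts <- attributes(classes)[c("q1", "q3", "cohort")]
  classes <- apply_force(classes, unique(forced_deg), "forced_deg")
  classes <- apply_force(classes, forced_prot, "forced_protein")
  rownames(classes) <- NULL
  attr(classes, "q1") <- atts$q1
  attr(classes, "q3") <- atts$q3
  attr(classes, "cohort") <- atts$cohort
  classes
}

#' Expression weight per reaction
#'
#' Evaluates each reaction's gene rule over per-gene tier scores with
#' OR -> max and AND -> min. Genes missing from `classes` are treated as
#' ABSENT; reactions with an empty rule (spontaneous/orphan) get weight 0.
#'
#' @param model A `metabolic_model`.
#' @param classes Classification data.frame.
#' @param tier_scores Named numeric with entries for all four tiers
#'   (default [default_tier_scores]).
#' @return Named numeric vector of weights, one per reaction.
#' @export
reaction_weights <- function(model, classes, tier_scores = default_tier_scores) {
  if (!all(EXPRESSION_TIERS %in% names(tier_scores))) {
    stop("tier_scores must name all four tiers", call. = FALSE)
  }
  gene_scores <- stats::setNames(unname(tier_scores[classes$tier]), classes$gene)
  w <- vapply(model$reactions$id, function(rid) {
    rule <- model$reactions$gene_rule[model$reactions$id == rid]
    evaluate_gene_rule(rule, gene_scores,
                       default = tier_scores[["ABSENT"]], empty = 0)
  }, numeric(1))
  stats::setNames(w, model$reactions$id)
}
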