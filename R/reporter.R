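## Reporter metabolite statistic.
##
## Each metabolite aggregates the differential-expression evidence of its
## neighboring enzyme genes (the genes appearing in the rules of reactions
## it participates in) by a Stouffer sum, Z_met = sum(Z_g)/sqrt(k), and is
## corrected against a Monte Carlo background of random size-k gene sets
## drawn from all scored model genes: z_corrected = (z_raw - mu_k)/sigma_k,
## p_reporter = 1 - Phi(z_corrected).

#' Neighbor genes of a metabolite
#'
#' Union of gene ids appearing (flattened, AND/OR structure ignored) in the
#' gene rules of all reactions whose stoichiometry includes the metabolite.
#' Compartment-specific: `glutamate[c]` and `glutamate[m]` have independent
#' neighborhoods.
#'
#' @param model A `metabolic_model`.
#' @param metabolite Metabolite id (with compartment bracket).
#' @return Character vector of gene ids (possibly empty).
#' @export
neighbor_genes <- function(model, metabolite) {
  if (!metabolite %in% model$metabolites$id) {
    stop(sprintf("metabolite '%s' not in model", metabolite), call. = FALSE)
  }
  touching <- vapply(model$reactions$id, function(rid) {
    metabolite %in% names(model$stoichiometry[[rid]])
  }, logical(1))
  rules <- model$reactions$gene_rule[touching]
  sort(unique(unlist(lapply(rules, rule_genes))))
}

#' Mode-transformed gene p-values
#'
#' Converts two-sided differential-expression p-values into the per-gene
#' scores fed to the reporter statistic. `all` leaves p unchanged; `up`
#' converts to the one-sided p for up-regulation (`p/2` when `log2fc > 0`,
#' `1 - p/2` otherwise); `down` is the mirror image. Genes with a log2 fold
#' change of exactly 0 get p = 0.5 in the directional modes. Outputs are
#' clipped to `[clip, 1 - clip]` so gene Z-scores stay finite.
#'
#' An alternative directional convention is restriction: keep only the genes
#' significant below `restrict_alpha` whose fold change matches the mode,
#' with p passed through untransformed. Neither convention is privileged;
#' the one-sided transform is the default.
#'
#' @param deg Differential-expression data.frame (`gene`, `log2fc`, `p`).
#' @param mode `"all"`, `"up"` or `"down"`.
#' @param clip Clipping bound (default `1e-15`).
#' @param restrict_alpha If non-`NULL` and mode is directional, restrict to
#'   direction-matching genes with `p < restrict_alpha` instead of applying
#'   the one-sided transform.
#' @return data.frame with columns `gene`, `p`; attribute `mode`.
#' @export
directional_pvalues <- function(deg, mode = c("all", "up", "down"),
                                clip = 1e-15, restrict_alpha = NULL) {
  mode <- match.arg(mode)
  if (!is.null(restrict_alpha) && mode != "all") {
    keep <- deg$p < restrict_alpha &
      (if (mode == "up") deg$log2fc > 0 else deg$log2fc < 0)
    deg <- deg[keep, , drop = FALSE]
    p <- pmin(pmax(deg$p, clip), 1 - clip)
    out <- data.frame(gene = deg$gene, p = p, stringsAsFactors = FALSE)
    attr(out, "mode") <- mode
    return(out)
  }
  p <- deg$p
  if (mode != "all") {
    fc <- deg$log2fc
    zero <- fc == 0
    if (any(zero)) {
      message(sprintf("directional_pvalues: %d gene(s) with log2fc == 0 set to p = 0.5",
                      sum(zero)))
    }
    if (mode == "up") {
      p <- ifelse(fc > 0, p / 2, 1 - p / 2)
    } else {
      p <- ifelse(fc < 0, p / 2, 1 - p / 2)
    }
    p[zero] <- 0.5
  }
  p <- pmin(pmax(p, clip), 1 - clip)
  out <- data.frame(gene = deg$gene, p = p, stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  out
}

#' Reporter metabolite scores
#'
#' @param model A `metabolic_model`.
#' @param scores Gene score data.frame from [directional_pvalues()] (columns
#'   `gene`, `p`; attribute `mode`). Genes absent from the model are dropped
#'   from both the metabolite sums and the background universe.
#' @param n_background Monte Carlo draws per distinct neighbor-set size
#'   (default 10000).
#' @param seed Integer seed; identical seeds give bit-identical results.
#' @return List with `records` (data.frame: `metabolite`, `compartment`,
#'   `k`, `z_raw`, `z_corrected`, `p_reporter`, `mode`, sorted by
#'   `p_reporter`) and `background` (data.frame: `k`, `mu`, `sigma`,
#'   `n_draws`, `sigma_floored`).
#' @export
reporter_scores <- function(model, scores, n_background = 10000, seed) {
  if (missing(seed)) stop("reporter_scores requires an explicit seed", call. = FALSE)
  mode <- attr(scores, "mode") %||% "all"
  scores <- scores[scores$gene %in% model$genes, , drop = FALSE]
  if (nrow(scores) == 0) stop("no scored gene is present in the model", call. = FALSE)
  if (anyDuplicated(scores$gene)) stop("duplicate genes in scores", call. = FALSE)
  gene_z <- stats::setNames(stats::qnorm(1 - scores$p), scores$gene)

  neighborhoods <- lapply(model$metabolites$id, function(met) {
    intersect(neighbor_genes(model, met), names(gene_z))
  })
  names(neighborhoods) <- model$metabolites$id
  neighborhoods <- neighborhoods[vapply(neighborhoods, length, integer(1)) >= 1]
  if (length(neighborhoods) == 0) {
    stop("no metabolite has a scored neighbor gene", call. = FALSE)
  }
  ks <- vapply(neighborhoods, length, integer(1))
  if (any(ks > length(gene_z))) {
    stop("neighbor set larger than the scored gene universe", call. = FALSE)
  }

  z_pop <- unname(gene_z)
  background <- with_seed(seed, {
    do.call(rbind, lapply(sort(unique(ks)), function(k) {
      draws <- vapply(seq_len(n_background), function(i) {
        sum(z_pop[sample.int(length(z_pop), k)])
      }, numeric(1)) / sqrt(k)
      mu <- mean(draws)
      sg <- stats::sd(draws)
      floored <- FALSE
      if (!is.finite(sg) || sg < 1e-12) {
        sg <- 1e-12
        floored <- TRUE
        warning(sprintf("background sigma for k = %d floored at 1e-12", k),
                call. = FALSE)
      }
      data.frame(k = k, mu = mu, sigma = sg, n_draws = n_background,
                 sigma_floored = floored)
    }))
  })

  z_raw <- vapply(neighborhoods, function(g) sum(gene_z[g]) / sqrt(length(g)),
                  numeric(1))
  mu_k <- background$mu[match(ks, background$k)]
  sigma_k <- background$sigma[match(ks, background$k)]
  z_corr <- (z_raw - mu_k) / sigma_k
  records <- data.frame(
    metabolite = names(neighborhoods),
    compartment = compartment_of(names(neighborhoods)),
    k = unname(ks),
    z_raw = unname(z_raw),
    z_corrected = unname(z_corr),
    p_reporter = 1 - stats::pnorm(z_corr),
    mode = mode,
    stringsAsFactors = FALSE)
  records <- records[order(records$p_reporter, records$metabolite), , drop = FALSE]
  rownames(records) <- NULL
  list(records = records, background = background)
}

#' Filter reporter records by significance
#'
#' @param records Reporter record data.frame.
#' @param alpha Significance cutoff (strict `<`; default 0.1).
#' @return Filtered data.frame, input order preserved.
#' @export
significant_reporters <- function(records, alpha = 0.1) {
  records[records$p_reporter < alpha, , drop = FALSE]
}
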