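## Metabolomics validation arm: pooled-QC based filtering, batch median
## synchronization, differential abundance calling and metabolite-category
## permutation tests.

#' Construct a metabolomics matrix
#'
#' @param abundance Numeric matrix, metabolites x samples (nonnegative or
#'   `NA` for undetected), with rownames and colnames.
#' @param samples data.frame with columns `sample`, `batch`, `sample_type`
#'   (`"QC"` or `"primary"`) and `group` (two group labels for primary
#'   samples, `"none"` for QC).
#' @return A `metabolomics_matrix` object.
#' @export
metabolomics_matrix <- function(abundance, samples) {
  abundance <- as.matrix(abundance)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(!is.null(rownames(abundance)), !is.null(colnames(abundance)))
  if (!identical(colnames(abundance), samples$sample)) {
    samples <- samples[match(colnames(abundance), samples$sample), , drop = FALSE]
  }
  if (any(is.na(samples$sample))) stop("sample annotation incomplete", call. = FALSE)
  if (!all(samples$sample_type %in% c("QC", "primary"))) {
    stop("sample_type must be 'QC' or 'primary'", call. = FALSE)
  }
  if (any(samples$sample_type == "QC" & samples$group != "none")) {
    stop("QC samples must have group = 'none'", call. = FALSE)
  }
  if (any(samples$sample_type == "primary" & samples$group == "none")) {
    stop("primary samples must have a group", call. = FALSE)
  }
  if (any(abundance < 0, na.rm = TRUE)) stop("abundances must be nonnegative", call. = FALSE)
  structure(list(abundance = abundance, samples = samples),
            class = "metabolomics_matrix")
}

#' @export
print.metabolomics_matrix <- function(x, ...) {
  cat(sprintf("metabolomics_matrix: %d metabolites x %d samples (%d QC, %d primary; %d batches)\n",
              nrow(x$abundance), ncol(x$abundance),
              sum(x$samples$sample_type == "QC"),
              sum(x$samples$sample_type == "primary"),
              length(unique(x$samples$batch))))
  invisible(x)
}

#' Read/write the metabolomics TSV dialect
#'
#' The file has a header row of sample ids (first column `metabolite`),
#' three attribute rows `!batch`, `!sample_type`, `!group`, then one row
#' per metabolite.
#'
#' @param path File path.
#' @return A `metabolomics_matrix`.
#' @export
read_metabolomics <- function(path) {
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  attr_rows <- raw[[1]] %in% c("!batch", "!sample_type", "!group")
  ann <- raw[attr_rows, , drop = FALSE]
  dat <- raw[!attr_rows, , drop = FALSE]
  sample_ids <- colnames(raw)[-1]
  get_row <- function(key) unlist(ann[ann[[1]] == key, -1, drop = TRUE])
  samples <- data.frame(sample = sample_ids,
                        batch = as.character(get_row("!batch")),
                        sample_type = as.character(get_row("!sample_type")),
                        group = as.character(get_row("!group")),
                        stringsAsFactors = FALSE)
  ab <- as.matrix(dat[, -1, drop = FALSE])
  mode(ab) <- "numeric"
  rownames(ab) <- dat[[1]]
  metabolomics_matrix(ab, samples)
}

#' @rdname read_metabolomics
#' @param m A `metabolomics_matrix`.
#' @export
write_metabolomics <- function(m, path) {
  header <- c("metabolite", m$samples$sample)
  lines <- c(paste(header, collapse = "\t"),
             paste(c("!batch", m$samples$batch), collapse = "\t"),
             paste(c("!sample_type", m$samples$sample_type), collapse = "\t"),
             paste(c("!group", m$samples$group), collapse = "\t"))
  body <- apply(cbind(rownames(m$abundance),
                      format(m$abundance, trim = TRUE, digits = 15)), 1,
                paste, collapse = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' QC filtering of a metabolomics matrix
#'
#' Removes metabolites undetected (missing) in more than `max_missing_frac`
#' of all samples, and metabolites whose relative standard deviation
#' (SD/mean over the pooled-QC samples) exceeds `max_rsd`.
#'
#' @param m A `metabolomics_matrix`.
#' @param max_missing_frac Missingness threshold (default 0.20).
#' @param max_rsd RSD threshold (default 0.50). Skipped with a warning when
#'   there are no QC samples.
#' @return List with `matrix` (filtered `metabolomics_matrix`) and
#'   `excluded` (data.frame `metabolite`, `rule`, `value`).
#' @export
qc_filter <- function(m, max_missing_frac = 0.20, max_rsd = 0.50) {
  ab <- m$abundance
  miss <- rowMeans(is.na(ab))
  qc_cols <- m$samples$sample_type == "QC"
  if (!any(qc_cols)) {
    warning("no QC samples: RSD rule skipped", call. = FALSE)
    rsd <- rep(NA_real_, nrow(ab))
  } else {
    qc <- ab[, qc_cols, drop = FALSE]
    rsd <- apply(qc, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2 || mean(v) == 0) return(NA_real_)
      stats::sd(v) / mean(v)
    })
  }
  bad_miss <- miss > max_missing_frac
  bad_rsd <- !is.na(rsd) & rsd > max_rsd
  excluded <- data.frame(
    metabolite = c(rownames(ab)[bad_miss], rownames(ab)[bad_rsd & !bad_miss]),
    rule = c(rep("missingness", sum(bad_miss)), rep("rsd", sum(bad_rsd & !bad_miss))),
    value = c(unname(miss[bad_miss]), unname(rsd[bad_rsd & !bad_miss])),
    stringsAsFactors = FALSE)
  keep <- !(bad_miss | bad_rsd)
  out <- m
  out$abundance <- ab[keep, , drop = FALSE]
  rownames(excluded) <- NULL
  list(matrix = out, excluded = excluded)
}

#' Batch correction by QC median synchronization
#'
#' Per metabolite and batch, all values are multiplied by
#' `global QC median / batch QC median`, equalizing the per-batch QC
#' medians. Single-batch input is returned unchanged; metabolites whose
#' batch QC median is zero (or missing) are flagged and left uncorrected in
#' that batch.
#'
#' @param m A `metabolomics_matrix`.
#' @return List with `matrix` (corrected) and `flagged` (data.frame
#'   `metabolite`, `batch`).
#' @export
batch_correct <- function(m) {
  batches <- unique(m$samples$batch)
  flagged <- data.frame(metabolite = character(0), batch = character(0),
                        stringsAsFactors = FALSE)
  if (length(batches) <= 1) return(list(matrix = m, flagged = flagged))
  ab <- m$abundance
  qc_cols <- m$samples$sample_type == "QC"
  if (!any(qc_cols)) stop("batch_correct requires QC samples", call. = FALSE)
  for (met in rownames(ab)) {
    global_med <- stats::median(ab[met, qc_cols], na.rm = TRUE)
    if (is.na(global_med) || global_med == 0) {
      flagged <- rbind(flagged, data.frame(metabolite = met, batch = "*",
                                           stringsAsFactors = FALSE))
      next
    }
    for (b in batches) {
      in_b <- m$samples$batch == b
      bmed <- stats::median(ab[met, qc_cols & in_b], na.rm = TRUE)
      if (is.na(bmed) || bmed == 0) {
        flagged <- rbind(flagged, data.frame(metabolite = met, batch = b,
                                             stringsAsFactors = FALSE))
        next
      }
      ab[met, in_b] <- ab[met, in_b] * (global_med / bmed)
    }
  }
  out <- m
  out$abundance <- ab
  list(matrix = out, flagged = flagged)
}

#' Differential metabolite abundance between two groups
#'
#' Per metabolite: Shapiro-Wilk normality at 0.05 in each group; when both
#' groups are normal a two-sample Student t-test, otherwise a two-tailed
#' Wilcoxon rank-sum test (exact for small tie-free samples, normal
#' approximation with tie correction otherwise). P-values are BH-adjusted
#' across all tested metabolites; a metabolite is called `up`/`down` when
#' `p_adj < alpha_adj`, with the direction given by the sign of the group
#' median difference (case minus control).
#'
#' @param m A `metabolomics_matrix` (filtered and batch corrected).
#' @param case,control Group labels; default the two non-`"none"` labels in
#'   sorted order with the second as case (set explicitly for real data).
#' @param alpha_adj Adjusted-p cutoff (default 0.1).
#' @return data.frame with `metabolite`, `call`, `test`, `p`, `p_adj`,
#'   `median_case`, `median_control`.
#' @export
differential_abundance <- function(m, case = NULL, control = NULL,
                                   alpha_adj = 0.1) {
  groups <- sort(setdiff(unique(m$samples$group), "none"))
  if (length(groups) != 2 && (is.null(case) || is.null(control))) {
    stop("need exactly two groups (or explicit case/control labels)", call. = FALSE)
  }
  if (is.null(control)) control <- groups[1]
  if (is.null(case)) case <- groups[2]
  ci <- m$samples$group == case
  ki <- m$samples$group == control
  if (sum(ci) < 3 || sum(ki) < 3) stop("each group needs n >= 3", call. = FALSE)
  rows <- lapply(rownames(m$abundance), function(met) {
    x <- m$abundance[met, ci]; x <- x[!is.na(x)]
    y <- m$abundance[met, ki]; y <- y[!is.na(y)]
    if (length(x) < 3 || length(y) < 3) {
      return(data.frame(metabolite = met, test = NA_character_, p = NA_real_,
                        median_case = stats::median(x), median_control = stats::median(y),
                        stringsAsFactors = FALSE))
    }
    if (stats::sd(c(x, y)) == 0) {
      return(data.frame(metabolite = met, test = "degenerate", p = 1,
                        median_case = stats::median(x), median_control = stats::median(y),
                        stringsAsFactors = FALSE))
    }
    normal <- function(v) {
      if (stats::sd(v) == 0) return(FALSE)
      stats::shapiro.test(v)$p.value > 0.05
    }
    if (normal(x) && normal(y)) {
      p <- stats::t.test(x, y, var.equal = TRUE)$p.value
      test <- "t"
    } else {
      p <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL)$p.value)
      test <- "wilcoxon"
    }
    data.frame(metabolite = met, test = test, p = p,
               median_case = stats::median(x), median_control = stats::median(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- rep(NA_real_, nrow(out))
  tested <- !is.na(out$p)
  out$p_adj[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  diff <- out$median_case - out$median_control
  out$call <- "unchanged"
  sig <- tested & out$p_adj < alpha_adj & diff != 0
  out$call[sig & diff > 0] <- "up"
  out$call[sig & diff < 0] <- "down"
  out[, c("metabolite", "call", "test", "p", "p_adj",
          "median_case", "median_control")]
}

#' Permutation test for category enrichment of dysregulation calls
#'
#' The statistic is the number of metabolites in the category whose call
#' matches `direction`. The null permutes the call vector across all
#' metabolites with category membership fixed; the over-representation
#' p-value is `(1 + #(perm >= obs)) / (1 + n_perm)` and the
#' under-representation tail uses `<=`.
#'
#' @param calls data.frame from [differential_abundance()].
#' @param categories Named character vector or data.frame
#'   (`metabolite`, `category`) mapping metabolites to categories.
#' @param direction `"up"` or `"down"`.
#' @param n_perm Number of permutations (default 100000).
#' @param seed Integer seed (required).
#' @return data.frame with `category`, `n_in_category`,
#'   `n_dysregulated_in_category`, `direction`, `p_perm_over`,
#'   `p_perm_under`, `n_perm`.
#' @export
category_permutation_test <- function(calls, categories,
                                      direction = c("up", "down"),
                                      n_perm = 100000, seed) {
  direction <- match.arg(direction)
  if (missing(seed)) stop("category_permutation_test requires an explicit seed", call. = FALSE)
  if (is.data.frame(categories)) {
    categories <- stats::setNames(categories$category, categories$metabolite)
  }
  cat_map <- categories[calls$metabolite]
  hit <- calls$call == direction
  cats <- sort(unique(stats::na.omit(unname(cat_map))))
  with_seed(seed, {
    rows <- lapply(cats, function(cc) {
      members <- which(!is.na(cat_map) & cat_map == cc)
      n_cat <- length(members)
      if (n_cat == 0) {
        warning(sprintf("category '%s' has no members; skipped", cc), call. = FALSE)
        return(NULL)
      }
      obs <- sum(hit[members])
      perm <- vapply(seq_len(n_perm), function(i) {
        sum(sample(hit)[members])
      }, numeric(1))
      data.frame(category = cc, n_in_category = n_cat,
                 n_dysregulated_in_category = obs, direction = direction,
                 p_perm_over = (1 + sum(perm >= obs)) / (1 + n_perm),
                 p_perm_under = (1 + sum(perm <= obs)) / (1 + n_perm),
                 n_perm = n_perm, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
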