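## End-to-end orchestration: classify -> force_high -> reaction_weights ->
## extract -> signature -> reporter (3 modes) -> subnetwork -> topology ->
## metabolomics, each stage writing its TSV/JSON outputs plus a log with
## seeds, so a run is reproducible bit-for-bit from its config.

pipeline_defaults <- function() {
  list(
    out_dir = "gemreporter_out",
    seed = 1L,
    ## input paths (NULL = use the synthetic scenario)
    model_path = NULL, model_format = "tabular",
    expression_primary = NULL, expression_support = NULL,
    deg_path = NULL, protein_path = NULL, tasks_path = NULL,
    metabolomics_path = NULL, categories_path = NULL,
    simulate = TRUE,
    run_metabolomics = TRUE,
    scenario = NULL,
    ## thresholds
    q_low = 0.25, q_high = 0.75, absent_sample_frac = 0.80,
    p_adj_force = 0.001, p_adj_sig = 0.01,
    reporter_alpha = 0.1, n_background = 10000,
    alpha_adj = 0.1, n_perm = 100000,
    epsilon = 1e-4, big_m = 1000,
    exchange_weight = 1,
    tier_scores = as.list(default_tier_scores),
    currency = default_currency_metabolites,
    reaction_penalty = -0.1,
    annealing = list(iterations = 20000, t0 = 1, cooling = 0.9995),
    top_k = 5,
    case = NULL, control = NULL,
    drop_patterns = character(0))
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; thresholds are checked to lie in their valid
#' ranges. The resolved configuration is echoed into the output directory
#' by [run_pipeline()].
#'
#' @param ... Named overrides of the defaults, or a single list/YAML file
#'   path as first unnamed argument.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args))) {
    x <- args[[1]]
    if (is.character(x) && length(x) == 1) x <- yaml::read_yaml(x)
    args <- x
  }
  cfg <- pipeline_defaults()
  unknown <- setdiff(names(args), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(args)] <- args
  in01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop(sprintf("config '%s' must lie in (0, 1)", key), call. = FALSE)
    }
  }
  for (key in c("q_low", "q_high", "absent_sample_frac", "p_adj_force",
                "p_adj_sig", "reporter_alpha", "alpha_adj")) in01(key)
  if (cfg$q_low >= cfg$q_high) stop("q_low must be < q_high", call. = FALSE)
  if (cfg$epsilon <= 0) stop("epsilon must be positive", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  cat(line, "\n", file = state$log_path, append = TRUE)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on either user-supplied input files or (default)
#' the synthetic scenario, writing each stage's tables and a JSON summary
#' under `config$out_dir`. Re-running with an identical config reproduces
#' all outputs.
#'
#' @param config A `pipeline_config` (or arguments forwarded to
#'   [pipeline_config()]).
#' @return Invisibly, a list with the in-memory stage results
#'   (`model`, `classes`, `weights`, `extraction`, `signature`,
#'   `reporter` (per mode), `graph`, `subnetwork`, `centrality`, `hubs`,
#'   `hub_report`, `metabolomics`, `truth`, `out_dir`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list(log_path = file.path(config$out_dir, "pipeline.log"))
  cat("", file = state$log_path)
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))],
                   file.path(config$out_dir, "config_resolved.yaml"))
  res <- list(out_dir = config$out_dir)

  ## ---- inputs ----
  scenario <- config$scenario %||% synthetic_scenario(seed = config$seed)
  if (!is.null(config$model_path)) {
    model <- read_model(config$model_path, config$model_format)
    pipeline_log(state, "model: read %d reactions from %s",
                 nrow(model$reactions), config$model_path)
  } else {
    model <- generate_toy_model(scenario)
    pipeline_log(state, "model: simulated (%d reactions, seed %d)",
                 nrow(model$reactions), scenario$seed)
  }
  truth <- attr(model, "truth")
  if (!is.null(config$expression_primary)) {
    prim <- as.matrix(read_tsv_frame_matrix(config$expression_primary))
    supp <- if (!is.null(config$expression_support)) {
      as.matrix(read_tsv_frame_matrix(config$expression_support))
    } else NULL
    deg <- read_tsv_table(config$deg_path)
    expr_truth <- NULL
  } else {
    gen <- generate_expression(model, scenario)
    prim <- gen$primary; supp <- gen$support; deg <- gen$deg
    expr_truth <- gen$truth
    truth <- c(truth, expr_truth)
  }
  proteins <- if (!is.null(config$protein_path)) {
    read_tsv_table(config$protein_path)$gene
  } else NULL
  tasks <- if (!is.null(config$tasks_path)) read_tasks(config$tasks_path) else list()
  write_model(model, file.path(config$out_dir, "model"))
  res$model <- model
  res$truth <- truth

  ## ---- expression tiers ----
  classes <- classify_genes(prim, config$absent_sample_frac,
                            config$q_low, config$q_high, cohort = "primary")
  if (!is.null(supp)) {
    classes <- combine_classes(classes,
                               classify_genes(supp, config$absent_sample_frac,
                                              config$q_low, config$q_high,
                                              cohort = "support"))
  }
  classes <- force_high(classes, deg, config$p_adj_force, proteins, quiet = TRUE)
  write_tsv_table(classes, file.path(config$out_dir, "gene_classes.tsv"))
  pipeline_log(state, "classify: %s",
               paste(sprintf("%s=%d", names(table(classes$tier)),
                             as.integer(table(classes$tier))), collapse = " "))
  res$classes <- classes

  ## ---- extraction ----
  weights <- reaction_weights(model, classes, unlist(config$tier_scores))
  ## exchange reactions (no gene rule, one-sided stoichiometry) are network
  ## plumbing: give them a small positive weight so the extracted model
  ## keeps its boundaries
  is_exchange <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    all(st > 0) || all(st < 0)
  }, logical(1))
  weights[is_exchange & weights == 0] <- config$exchange_weight
  extraction <- extract_context_model(model, weights, tasks,
                                      epsilon = config$epsilon,
                                      big_m = config$big_m)
  write_model(extraction$sub_model, file.path(config$out_dir, "context_model"))
  jsonlite::write_json(list(kept = extraction$kept,
                            objective = extraction$objective,
                            task_report = as.list(extraction$task_report)),
                       file.path(config$out_dir, "extraction.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  pipeline_log(state, "extract: kept %d/%d reactions (objective %.3f)",
               length(extraction$kept), nrow(model$reactions),
               extraction$objective)
  res$extraction <- extraction
  res$weights <- weights

  sig <- gem_signature(extraction$sub_model, deg, config$p_adj_sig)
  jsonlite::write_json(sig, file.path(config$out_dir, "gem_signature.json"),
                       auto_unbox = FALSE, pretty = TRUE)
  res$signature <- sig

  ## ---- reporter metabolites (3 modes) ----
  sub_model <- extraction$sub_model
  reporter <- list()
  for (mode in c("all", "up", "down")) {
    scores <- suppressMessages(directional_pvalues(deg, mode))
    rs <- reporter_scores(sub_model, scores, config$n_background,
                          seed = config$seed + match(mode, c("all", "up", "down")))
    write_tsv_table(rs$records,
                    file.path(config$out_dir, sprintf("reporter_%s.tsv", mode)))
    reporter[[mode]] <- rs
    pipeline_log(state, "reporter[%s]: %d metabolites, %d significant at %.2g",
                 mode, nrow(rs$records),
                 nrow(significant_reporters(rs$records, config$reporter_alpha)),
                 config$reporter_alpha)
  }
  res$reporter <- reporter
  all_records <- do.call(rbind, lapply(reporter, `[[`, "records"))

  ## ---- subnetwork ----
  graph <- build_graph(sub_model, config$currency)
  graph <- score_nodes(graph, all_records, config$reaction_penalty)
  subnet <- search_subnetwork(graph,
                              iterations = config$annealing$iterations,
                              t0 = config$annealing$t0,
                              cooling = config$annealing$cooling,
                              seed = config$seed + 11L)
  export_subnetwork(subnet, graph, config$out_dir,
                    drop_patterns = config$drop_patterns)
  pipeline_log(state, "subnetwork: %d nodes (score %.3f), major component %d nodes",
               length(subnet$selected), subnet$score, length(subnet$major))
  res$graph <- graph
  res$subnetwork <- subnet

  ## ---- topology ----
  cent <- centrality(subnet$major_graph)
  write_tsv_table(cent, file.path(config$out_dir, "centrality.tsv"))
  hubs <- top_hubs(cent, config$top_k, "metabolite")
  hub_report <- annotate_hubs(hubs, all_records, cent)
  write_tsv_table(hub_report, file.path(config$out_dir, "hub_report.tsv"))
  pipeline_log(state, "topology: %d hub metabolite(s): %s",
               length(hubs), paste(utils::head(hubs, 5), collapse = ", "))
  res$centrality <- cent
  res$hubs <- hubs
  res$hub_report <- hub_report

  ## ---- metabolomics arm (optional) ----
  metab <- NULL
  if (!isTRUE(config$run_metabolomics)) {
    mm <- NULL
  } else if (!is.null(config$metabolomics_path)) {
    mm <- read_metabolomics(config$metabolomics_path)
    categories <- read_tsv_table(config$categories_path)
  } else if (isTRUE(config$simulate)) {
    genm <- generate_metabolomics(model, scenario)
    mm <- genm$matrix
    categories <- genm$categories
    res$truth$metabolomics <- genm$truth
  } else {
    mm <- NULL
  }
  if (!is.null(mm)) {
    qf <- qc_filter(mm)
    bc <- batch_correct(qf$matrix)
    calls <- differential_abundance(bc$matrix, case = config$case,
                                    control = config$control,
                                    alpha_adj = config$alpha_adj)
    write_tsv_table(calls, file.path(config$out_dir, "differential_abundance.tsv"))
    cat_res <- do.call(rbind, lapply(c("up", "down"), function(dir) {
      category_permutation_test(calls, categories, dir,
                                n_perm = config$n_perm,
                                seed = config$seed + 21L + (dir == "down"))
    }))
    write_tsv_table(cat_res, file.path(config$out_dir, "category_tests.tsv"))
    pipeline_log(state, "metabolomics: %d tested, %d up / %d down calls",
                 nrow(calls), sum(calls$call == "up"), sum(calls$call == "down"))
    metab <- list(filtered = qf, corrected = bc$matrix, calls = calls,
                  category_tests = cat_res)
  } else {
    pipeline_log(state, "metabolomics: no inputs, arm skipped")
  }
  res$metabolomics <- metab

  pipeline_log(state, "done: outputs in %s", config$out_dir)
  invisible(res)
}

## expression TSV: first column gene id, remaining columns samples
read_tsv_frame_matrix <- function(path) {
  tab <- read_tsv_table(path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}
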