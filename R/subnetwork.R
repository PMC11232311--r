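## Reporter-enriched subnetwork search on the bipartite metabolite-reaction
## graph. Currency metabolites (ATP, H2O, NAD+, ...) are removed before any
## topology work because they connect unrelated pathways and would dominate
## every centrality and subnetwork score.

#' Currency metabolite names removed by default
#'
#' Matched case-insensitively against both the metabolite name and the id
#' prefix before the compartment bracket, in every compartment.
#' @export
default_currency_metabolites <- c(
  "H2O", "CO2", "O2", "H+", "HCO3-", "Na+", "CoA", "Pi", "PPi", "AMP",
  "ADP", "ATP", "NAD+", "NADH", "NADP+", "NADPH", "PAP", "PAPS", "FAD",
  "FADH2")

#' Build the bipartite metabolite-reaction graph
#'
#' Nodes are metabolites and reactions; an undirected edge joins a
#' metabolite to every reaction in which it has a nonzero coefficient.
#' Currency metabolites are dropped in all compartments, and reactions left
#' with no participants are dropped too. Metabolites participating in no
#' retained reaction do not appear.
#'
#' @param model A `metabolic_model`.
#' @param currency Character vector of currency metabolite names (default
#'   [default_currency_metabolites]); use `character(0)` to keep everything.
#' @return An `igraph` graph with vertex attributes `type`
#'   (`"metabolite"`/`"reaction"`) and `name`.
#' @export
build_graph <- function(model, currency = default_currency_metabolites) {
  cur <- toupper(currency)
  met_ids <- model$metabolites$id
  is_cur <- toupper(strip_compartment(met_ids)) %in% cur |
    toupper(model$metabolites$name) %in% cur
  currency_ids <- met_ids[is_cur]
  edges <- character(0)
  for (rid in model$reactions$id) {
    participants <- setdiff(names(model$stoichiometry[[rid]]), currency_ids)
    if (length(participants) == 0) next
    edges <- c(edges, rbind(participants, rid))
  }
  if (length(edges) == 0) {
    g <- igraph::make_empty_graph(directed = FALSE)
    return(g)
  }
  g <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                   directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% met_ids,
                              "metabolite", "reaction")
  g
}

#' Attach reporter-based scores to graph nodes
#'
#' Metabolite nodes score `qnorm(1 - p_reporter)`; metabolites with no
#' reporter record score 0 (the p = 0.5 null); reaction nodes get a flat
#' penalty so they are admitted only as bridges between scoring
#' metabolites. When a metabolite has records in several directional modes,
#' the smallest p wins.
#'
#' @param graph Bipartite graph from [build_graph()].
#' @param records Reporter record data.frame.
#' @param reaction_penalty Score of reaction nodes (default -0.1).
#' @return The graph with a numeric vertex attribute `score`.
#' @export
score_nodes <- function(graph, records, reaction_penalty = -0.1) {
  if (igraph::vcount(graph) == 0) return(graph)
  best_p <- tapply(records$p_reporter, records$metabolite, min)
  sc <- ifelse(igraph::V(graph)$type == "reaction", reaction_penalty, 0)
  idx <- match(igraph::V(graph)$name, names(best_p))
  has <- !is.na(idx) & igraph::V(graph)$type == "metabolite"
  sc[has] <- stats::qnorm(1 - unname(best_p)[idx[has]])
  igraph::V(graph)$score <- sc
  graph
}

#' Simulated annealing search for the maximal-scoring subnetwork
#'
#' The state is a node-inclusion vector; a move toggles one uniformly
#' chosen node; the aggregate score of a selected set A is
#' `S(A) = sum(scores in A) / sqrt(|A|)` (empty sets score `-Inf`). Uphill
#' moves are always accepted, downhill moves with probability
#' `exp(dS / T)` under a geometric cooling schedule. The best state ever
#' seen is returned, decomposed into connected components of the parent
#' graph; connectivity is not enforced during the search. The search starts
#' from the single best-scoring node, so the returned score is never below
#' the best single-node score.
#'
#' Because the aggregate score never rewards penalty-scored reaction nodes,
#' the raw optimum tends to contain metabolites only, which in a bipartite
#' graph are pairwise non-adjacent. With `bridge = TRUE` (default) the
#' component decomposition therefore also includes bridging reaction nodes
#' adjacent to at least two selected metabolites; the `selected` set and
#' `score` always refer to the raw annealing state.
#'
#' @param graph Scored graph from [score_nodes()].
#' @param iterations Number of moves (default 20000).
#' @param t0 Initial temperature (default 1).
#' @param cooling Geometric cooling rate per iteration (default 0.9995).
#' @param seed Integer seed (required; same seed, same result).
#' @param bridge Include bridging reaction nodes in the component
#'   decomposition (default `TRUE`; ignored when the graph has no `type`
#'   attribute).
#' @return A `subnetwork_result`: list with `selected` (node names),
#'   `score`, `bridges` (reaction nodes added to the decomposition),
#'   `components` (list of name vectors, largest first), `major`
#'   (largest component names), `major_graph` (induced igraph), and `trace`
#'   (iterations, t0, cooling, seed, accepted moves).
#' @export
search_subnetwork <- function(graph, iterations = 20000, t0 = 1,
                              cooling = 0.9995, seed, bridge = TRUE) {
  if (missing(seed)) stop("search_subnetwork requires an explicit seed", call. = FALSE)
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(structure(list(selected = character(0), score = -Inf,
                          bridges = character(0),
                          components = list(), major = character(0),
                          major_graph = graph,
                          trace = list(iterations = iterations, t0 = t0,
                                       cooling = cooling, seed = seed,
                                       accepted = 0L)),
                     class = "subnetwork_result"))
  }
  sc <- igraph::V(graph)$score
  if (is.null(sc)) stop("graph has no 'score' vertex attribute; run score_nodes()", call. = FALSE)
  accepted <- 0L
  state <- logical(n)
  start <- which.max(sc)
  state[start] <- TRUE
  cur_sum <- sc[start]; cur_n <- 1L
  cur_S <- cur_sum
  best_state <- state; best_S <- cur_S
  res <- with_seed(seed, {
    temp <- t0
    picks <- sample.int(n, iterations, replace = TRUE)
    us <- stats::runif(iterations)
    for (it in seq_len(iterations)) {
      i <- picks[it]
      if (state[i]) {
        new_sum <- cur_sum - sc[i]; new_n <- cur_n - 1L
      } else {
        new_sum <- cur_sum + sc[i]; new_n <- cur_n + 1L
      }
      new_S <- if (new_n == 0L) -Inf else new_sum / sqrt(new_n)
      dS <- new_S - cur_S
      if (dS > 0 || us[it] < exp(dS / temp)) {
        state[i] <- !state[i]
        cur_sum <- new_sum; cur_n <- new_n; cur_S <- new_S
        accepted <- accepted + 1L
        if (cur_S > best_S) {
          best_S <- cur_S
          best_state <- state
        }
      }
      temp <- temp * cooling
    }
    list(best_state = best_state, best_S = best_S, accepted = accepted)
  })
  selected <- igraph::V(graph)$name[res$best_state]
  bridges <- character(0)
  decomposed <- selected
  vtype <- igraph::V(graph)$type
  if (isTRUE(bridge) && !is.null(vtype)) {
    rxn_nodes <- igraph::V(graph)$name[vtype == "reaction"]
    cand <- setdiff(rxn_nodes, selected)
    if (length(cand)) {
      n_sel_nbrs <- vapply(cand, function(rn) {
        nb <- igraph::neighbors(graph, rn)$name
        sum(nb %in% selected)
      }, numeric(1))
      bridges <- cand[n_sel_nbrs >= 2]
      decomposed <- c(selected, bridges)
    }
  }
  sub <- igraph::induced_subgraph(graph, decomposed)
  comp <- igraph::components(sub)
  comp_list <- split(igraph::V(sub)$name, comp$membership)
  comp_list <- comp_list[order(vapply(comp_list, length, integer(1)),
                               decreasing = TRUE)]
  names(comp_list) <- NULL
  major <- if (length(comp_list)) comp_list[[1]] else character(0)
  structure(list(selected = selected,
                 score = res$best_S,
                 bridges = bridges,
                 components = comp_list,
                 major = major,
                 major_graph = igraph::induced_subgraph(graph, major),
                 trace = list(iterations = iterations, t0 = t0,
                              cooling = cooling, seed = seed,
                              accepted = res$accepted)),
            class = "subnetwork_result")
}

#' @export
print.subnetwork_result <- function(x, ...) {
  cat(sprintf("subnetwork_result: %d nodes selected (score %.3f), %d component(s), major %d nodes / %d edges\n",
              length(x$selected), x$score, length(x$components),
              length(x$major), igraph::ecount(x$major_graph)))
  invisible(x)
}

#' Export a subnetwork for visualization
#'
#' Writes GraphML and SIF files of the selected subnetwork (Cytoscape
#' compatible) plus a TSV of connected components. `drop_patterns` filters
#' nodes out of the two visualization exports only; the component TSV (the
#' analysis output) always contains every selected node.
#'
#' @param result A `subnetwork_result`.
#' @param graph The scored parent graph.
#' @param dir Output directory (created if needed).
#' @param drop_patterns Character vector of regular expressions; matching
#'   node names are excluded from GraphML/SIF only.
#' @param basename File basename (default `"subnetwork"`).
#' @return Named character vector of the written paths, invisibly.
#' @export
export_subnetwork <- function(result, graph, dir, drop_patterns = character(0),
                              basename = "subnetwork") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  comp_id <- integer(0)
  for (i in seq_along(result$components)) {
    comp_id[result$components[[i]]] <- i
  }
  keep <- union(result$selected, result$bridges %||% character(0))
  if (length(drop_patterns)) {
    drop <- Reduce(`|`, lapply(drop_patterns, grepl, x = keep), rep(FALSE, length(keep)))
    keep <- keep[!drop]
  }
  sub <- igraph::induced_subgraph(graph, keep)
  igraph::V(sub)$component <- unname(comp_id[igraph::V(sub)$name])
  graphml_path <- file.path(dir, paste0(basename, ".graphml"))
  igraph::write_graph(sub, graphml_path, format = "graphml")
  ## SIF: one line per edge "source <relation> target"; isolated nodes alone
  el <- igraph::as_edgelist(sub)
  sif_lines <- if (nrow(el)) paste(el[, 1], "mr", el[, 2]) else character(0)
  isolated <- setdiff(igraph::V(sub)$name, unique(as.vector(el)))
  sif_path <- file.path(dir, paste0(basename, ".sif"))
  writeLines(c(sif_lines, isolated), sif_path)
  comp_path <- file.path(dir, paste0(basename, "_components.tsv"))
  all_nodes <- union(result$selected, result$bridges %||% character(0))
  comp_tab <- data.frame(node = all_nodes,
                         type = igraph::V(graph)$type[match(all_nodes, igraph::V(graph)$name)],
                         score = igraph::V(graph)$score[match(all_nodes, igraph::V(graph)$name)],
                         selected = all_nodes %in% result$selected,
                         component = unname(comp_id[all_nodes]),
                         stringsAsFactors = FALSE)
  write_tsv_table(comp_tab, comp_path)
  invisible(c(graphml = graphml_path, sif = sif_path, components = comp_path))
}
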