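## Topological hub ranking on the (possibly disconnected) reporter
## subnetwork: degree, closeness and betweenness on undirected unweighted
## shortest paths, ranked within node type.

#' Node centralities of a bipartite metabolic graph
#'
#' Degree is the incident edge count. Closeness uses the
#' component-size-corrected (Wasserman-Faust) form
#' `(r/(n-1)) * (r / sum(d))` where `r` is the number of reachable nodes
#' (excluding the node itself) and the sum runs over reachable nodes;
#' isolated nodes score 0. Betweenness is the raw count of shortest paths
#' passing through a node (endpoints excluded, pairs of both node types).
#' Ranks use competition ("min") ranking within node type, 1 = most
#' central.
#'
#' @param graph An `igraph` graph with a `type` vertex attribute.
#' @return data.frame with columns `node`, `type`, `degree`, `closeness`,
#'   `betweenness`, `rank_degree`, `rank_closeness`, `rank_betweenness`.
#' @export
centrality <- function(graph) {
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(data.frame(node = character(0), type = character(0),
                      degree = integer(0), closeness = numeric(0),
                      betweenness = numeric(0), rank_degree = integer(0),
                      rank_closeness = integer(0), rank_betweenness = integer(0),
                      stringsAsFactors = FALSE))
  }
  deg <- igraph::degree(graph)
  btw <- igraph::betweenness(graph, directed = FALSE, normalized = FALSE)
  d <- igraph::distances(graph)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  type <- igraph::V(graph)$type %||% rep("metabolite", n)
  out <- data.frame(node = igraph::V(graph)$name,
                    type = type,
                    degree = as.integer(deg),
                    closeness = clo,
                    betweenness = unname(btw),
                    stringsAsFactors = FALSE)
  out$rank_degree <- stats::ave(out$degree, out$type, FUN = rank_desc_min)
  out$rank_closeness <- stats::ave(out$closeness, out$type, FUN = rank_desc_min)
  out$rank_betweenness <- stats::ave(out$betweenness, out$type, FUN = rank_desc_min)
  rownames(out) <- NULL
  out
}

#' Top hub nodes by any centrality criterion
#'
#' Union of the top-`k` nodes of the requested type under each of the three
#' rank columns, duplicates collapsed, sorted by best rank then id.
#'
#' @param table Centrality table from [centrality()].
#' @param k Top count per criterion (default 5).
#' @param node_type `"metabolite"` or `"reaction"`.
#' @return Character vector of node ids.
#' @export
top_hubs <- function(table, k = 5, node_type = c("metabolite", "reaction")) {
  node_type <- match.arg(node_type)
  tab <- table[table$type == node_type, , drop = FALSE]
  if (k <= 0 || nrow(tab) == 0) return(character(0))
  picks <- unique(c(tab$node[tab$rank_degree <= k],
                    tab$node[tab$rank_closeness <= k],
                    tab$node[tab$rank_betweenness <= k]))
  best <- vapply(picks, function(nd) {
    row <- tab[tab$node == nd, ]
    min(row$rank_degree, row$rank_closeness, row$rank_betweenness)
  }, numeric(1))
  picks[order(best, picks)]
}

#' Annotate hub nodes with their reporter evidence
#'
#' Joins hub metabolites with their reporter record (directional mode and
#' p-value); the smallest-p record wins when several modes scored the
#' metabolite. Hubs without a record are marked `"n.s."`.
#'
#' @param hubs Character vector of node ids (from [top_hubs()]).
#' @param records Reporter record data.frame.
#' @param table Optional centrality table; when given, the three ranks are
#'   included.
#' @return data.frame with columns `metabolite`, `compartment`,
#'   `test_type` (`"Up"`/`"Down"`/`"All"`/`"n.s."`), `p_reporter` and,
#'   when `table` is supplied, `rank_degree`, `rank_closeness`,
#'   `rank_betweenness`.
#' @export
annotate_hubs <- function(hubs, records, table = NULL) {
  if (length(hubs) == 0) {
    out <- data.frame(metabolite = character(0), compartment = character(0),
                      test_type = character(0), p_reporter = numeric(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  rows <- lapply(hubs, function(h) {
    rec <- records[records$metabolite == h, , drop = FALSE]
    if (nrow(rec) == 0) {
      data.frame(metabolite = h, compartment = compartment_of(h),
                 test_type = "n.s.", p_reporter = NA_real_,
                 stringsAsFactors = FALSE)
    } else {
      rec <- rec[which.min(rec$p_reporter), ]
      label <- c(all = "All", up = "Up", down = "Down")[rec$mode]
      data.frame(metabolite = h, compartment = rec$compartment,
                 test_type = unname(label), p_reporter = rec$p_reporter,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (!is.null(table)) {
    idx <- match(out$metabolite, table$node)
    out$rank_degree <- table$rank_degree[idx]
    out$rank_closeness <- table$rank_closeness[idx]
    out$rank_betweenness <- table$rank_betweenness[idx]
  }
  rownames(out) <- NULL
  out
}

#' Project the bipartite graph onto metabolites
#'
#' Two metabolites are joined when they share a reaction. Provided as an
#' alternative substrate for [centrality()]; the bipartite graph is the
#' default elsewhere.
#'
#' @param graph Bipartite graph from [build_graph()].
#' @return An `igraph` graph of metabolite nodes.
#' @export
project_metabolites <- function(graph) {
  if (igraph::vcount(graph) == 0) return(graph)
  is_met <- igraph::V(graph)$type == "metabolite"
  g2 <- graph
  igraph::V(g2)$type <- !is_met  # logical type attr for bipartite_projection
  proj <- igraph::bipartite_projection(g2, which = "false")
  igraph::V(proj)$type <- "metabolite"
  proj
}
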