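## Fixtures and independent oracles shared across the test suite.
## Oracles deliberately avoid the code paths they check: centralities come
## from a Floyd-Warshall brute force, steady-state feasibility on the
## unit-conversion test networks from digraph reachability, BH from a
## literal step-up.

## ---- fixtures --------------------------------------------------------------

## the glutamate/glutamine three-reaction fixture (amidation, hydrolysis,
## mitochondrial carrier) with its enzyme genes
glutamate_fixture_model <- function() {
  mets <- data.frame(
    id = c("ATP[c]", "ADP[c]", "Pi[c]", "H2O[c]", "NH3[c]", "H+[c]", "H+[m]",
           "glutamate[c]", "glutamine[c]", "glutamate[m]",
           "aspartate[c]", "aspartate[m]"),
    stringsAsFactors = FALSE)
  mets$name <- gemreporter::strip_compartment(mets$id)
  mets$compartment <- gemreporter::compartment_of(mets$id)
  mets$is_currency <- mets$name %in% c("ATP", "ADP", "Pi", "H2O", "H+")
  mets$category <- NA_character_
  eq <- c(
    HMR_3890 = "ATP[c] + NH3[c] + glutamate[c] ⇒ ADP[c] + Pi[c] + glutamine[c]",
    HMR_9802 = "H2O[c] + glutamine[c] ⇒ NH3[c] + glutamate[c]",
    HMR_3825 = "H+[c] + aspartate[m] + glutamate[c] ⇒ H+[m] + aspartate[c] + glutamate[m]")
  rules <- c(HMR_3890 = "GLUL", HMR_9802 = "GLS",
             HMR_3825 = "SLC25A12 or SLC25A13")
  stoich <- list()
  rx <- lapply(names(eq), function(rid) {
    p <- gemreporter::parse_reaction_equation(eq[[rid]], rid)
    stoich[[rid]] <<- p$stoich
    data.frame(id = rid, gene_rule = rules[[rid]], subsystem = NA_character_,
               lb = 0, ub = 1000, reversible = p$reversible,
               stringsAsFactors = FALSE)
  })
  gemreporter::metabolic_model(mets, do.call(rbind, rx), stoich)
}

## small linear-chain model with exchanges: EX_A => A => B => C => EX_C
chain_model <- function() {
  mets <- data.frame(id = c("A[c]", "B[c]", "C[c]"),
                     name = c("A", "B", "C"), compartment = "c",
                     is_currency = FALSE, category = NA_character_,
                     stringsAsFactors = FALSE)
  stoich <- list(EX_A = c("A[c]" = 1),
                 R1 = c("A[c]" = -1, "B[c]" = 1),
                 R2 = c("B[c]" = -1, "C[c]" = 1),
                 EX_C = c("C[c]" = -1))
  rx <- data.frame(id = names(stoich), gene_rule = c("", "G1", "G2", ""),
                   subsystem = NA_character_, lb = 0, ub = 1000,
                   reversible = FALSE, stringsAsFactors = FALSE)
  gemreporter::metabolic_model(mets, rx, stoich)
}

## random linear pathway network for extraction tests: a guaranteed route
## source -> ... -> target plus optional decorations, all reactions optional
random_extraction_instance <- function(seed, n_chain = 4, n_extra = 3) {
  set.seed(seed)
  n_met <- n_chain + n_extra
  ids <- sprintf("m%d[c]", seq_len(n_met))
  mets <- data.frame(id = ids, name = gemreporter::strip_compartment(ids),
                     compartment = "c", is_currency = FALSE,
                     category = NA_character_, stringsAsFactors = FALSE)
  stoich <- list()
  add <- function(rid, st) stoich[[rid]] <<- st
  for (j in seq_len(n_chain - 1)) {
    add(sprintf("C%d", j), stats::setNames(c(-1, 1), ids[c(j, j + 1)]))
  }
  for (j in seq_len(n_extra)) {
    from <- sample(n_met, 1)
    to <- sample(setdiff(seq_len(n_met), from), 1)
    add(sprintf("X%d", j), stats::setNames(c(-1, 1), ids[c(from, to)]))
  }
  rx <- data.frame(id = names(stoich), gene_rule = "",
                   subsystem = NA_character_, lb = 0, ub = 1000,
                   reversible = FALSE, stringsAsFactors = FALSE)
  model <- gemreporter::metabolic_model(mets, rx, stoich)
  weights <- stats::setNames(round(stats::runif(nrow(rx), -5, 5), 1), rx$id)
  task <- gemreporter::metabolic_task("prod_target",
                                      stats::setNames(0.1, ids[n_chain]),
                                      allowed_uptakes = ids[1])
  list(model = model, weights = weights, task = task)
}

## random undirected graph as an igraph with type attribute
random_typed_graph <- function(seed, n_max = 30) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  p <- stats::runif(1, 0.08, 0.3)
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  igraph::V(g)$type <- sample(c("metabolite", "reaction"), n, replace = TRUE)
  list(graph = g, adj = adj)
}

## ---- oracles ---------------------------------------------------------------

## Floyd-Warshall all-pairs shortest paths with path counting; returns
## degree, Wasserman-Faust closeness and raw betweenness for an adjacency
## matrix. Entirely independent of igraph.
oracle_centrality <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  cnt <- matrix(0, n, n)
  d[adj == 1] <- 1
  cnt[adj == 1] <- 1
  diag(d) <- 0
  diag(cnt) <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (!is.finite(d[i, k]) || i == k) next
      for (j in seq_len(n)) {
        if (j == k || j == i || !is.finite(d[k, j])) next
        alt <- d[i, k] + d[k, j]
        if (alt < d[i, j] - 1e-9) {
          d[i, j] <- alt
          cnt[i, j] <- cnt[i, k] * cnt[k, j]
        } else if (abs(alt - d[i, j]) < 1e-9) {
          cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
        }
      }
    }
  }
  degree <- rowSums(adj)
  closeness <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach)
    if (r == 0 || n == 1) return(0)
    (r / (n - 1)) * (r / sum(reach))
  }, numeric(1))
  betweenness <- numeric(n)
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      if (!is.finite(d[i, j]) || cnt[i, j] == 0) next
      for (v in seq_len(n)) {
        if (v == i || v == j) next
        if (is.finite(d[i, v]) && is.finite(d[v, j]) &&
            abs(d[i, v] + d[v, j] - d[i, j]) < 1e-9) {
          betweenness[v] <- betweenness[v] + cnt[i, v] * cnt[v, j] / cnt[i, j]
        }
      }
    }
  }
  list(degree = degree, closeness = closeness, betweenness = betweenness)
}

## Combinatorial oracles for unit-conversion irreversible networks (every
## non-exchange reaction converts one metabolite into one other with unit
## coefficients). Steady-state feasibility questions then reduce to
## reachability in the reaction digraph -- a route fully independent of any
## LP code.

reaction_digraph <- function(model) {
  edges <- list(); sources <- character(0); sinks <- character(0)
  for (rid in model$reactions$id) {
    st <- model$stoichiometry[[rid]]
    subs <- names(st)[st < 0]; prods <- names(st)[st > 0]
    if (length(subs) == 0) {
      sources <- c(sources, prods)
    } else if (length(prods) == 0) {
      sinks <- c(sinks, subs)
    } else {
      for (a in subs) for (b in prods) {
        edges[[length(edges) + 1]] <- c(a, b)
      }
    }
  }
  list(edges = edges, sources = unique(sources), sinks = unique(sinks))
}

reachable_from <- function(edges, start) {
  seen <- unique(start)
  repeat {
    grew <- FALSE
    for (e in edges) {
      if (e[1] %in% seen && !(e[2] %in% seen)) {
        seen <- c(seen, e[2]); grew <- TRUE
      }
    }
    if (!grew) return(seen)
  }
}

## task feasibility: every required metabolite reachable from the task
## uptakes or the model's own uptake exchanges
oracle_task_feasible <- function(model, task) {
  dg <- reaction_digraph(model)
  feed <- union(dg$sources, task$allowed_uptakes)
  reach <- reachable_from(dg$edges, feed)
  all(names(task$required_production) %in% reach)
}

## per-reaction flux consistency: a conversion a -> b carries steady flux
## iff it sits on an uptake-to-secretion path or on a directed cycle;
## uptake (secretion) exchanges need their metabolite drained (fed)
oracle_flux_consistent <- function(model) {
  stopifnot(all(!model$reactions$reversible))
  dg <- reaction_digraph(model)
  fwd <- reachable_from(dg$edges, dg$sources)
  rev_edges <- lapply(dg$edges, rev)
  bwd <- reachable_from(rev_edges, dg$sinks)
  ok <- vapply(model$reactions$id, function(rid) {
    st <- model$stoichiometry[[rid]]
    subs <- names(st)[st < 0]; prods <- names(st)[st > 0]
    if (length(subs) == 0) {          # uptake: product must drain or cycle
      return(any(prods %in% bwd))
    }
    if (length(prods) == 0) {         # secretion: substrate must be fed
      return(any(subs %in% fwd))
    }
    a <- subs[1]; b <- prods[1]
    on_path <- a %in% fwd && b %in% bwd
    in_cycle <- a %in% reachable_from(dg$edges, b)
    on_path || in_cycle
  }, logical(1))
  model$reactions$id[ok]
}

## exhaustive-enumeration optimum for the extraction problem: maximize
## sum(w) over all reaction subsets keeping every task feasible (task
## feasibility via the reachability oracle; the reference metabolite set is
## preserved so task demands stay well-defined)
oracle_extraction_optimum <- function(model, weights, tasks) {
  rxn_ids <- model$reactions$id
  n <- length(rxn_ids)
  best <- -Inf; best_set <- NULL
  for (mask in 0:(2^n - 1)) {
    sel <- rxn_ids[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    val <- sum(weights[sel])
    if (val <= best) next
    sub <- gemreporter::metabolic_model(
      model$metabolites,
      model$reactions[model$reactions$id %in% sel, , drop = FALSE],
      model$stoichiometry[sel])
    ok <- all(vapply(tasks, function(tk) oracle_task_feasible(sub, tk),
                     logical(1)))
    if (ok) { best <- val; best_set <- sel }
  }
  list(objective = best, kept = best_set)
}

## exhaustive optimum of the subnetwork score over all nonempty subsets
oracle_subnetwork_optimum <- function(scores) {
  n <- length(scores)
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    sel <- bitwAnd(mask, 2^(seq_len(n) - 1)) > 0
    s <- sum(scores[sel]) / sqrt(sum(sel))
    if (s > best) best <- s
  }
  best
}

## literal Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in seq(m, 1)) {
    val <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

## exact two-sided Wilcoxon rank-sum p by full enumeration of label
## assignments (tie-free data)
oracle_wilcoxon_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)])
  ws <- apply(idx, 2, function(ii) sum(r[ii]))
  mu <- n1 * (length(pooled) + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
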