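test_that("currency metabolites are stripped from the bipartite graph", {
  m <- glutamate_fixture_model()
  g <- build_graph(m)
  nb <- igraph::neighbors(g, "HMR_3890")$name
  expect_setequal(nb, c("NH3[c]", "glutamate[c]", "glutamine[c]"))
  expect_false(any(c("ATP[c]", "ADP[c]", "Pi[c]", "H2O[c]") %in%
                     igraph::V(g)$name))
  ## bipartite: no metabolite-metabolite or reaction-reaction edges
  el <- igraph::as_edgelist(g)
  types <- stats::setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(types[el[, 1]] != types[el[, 2]]))
})

test_that("a reaction with only currency participants is dropped", {
  mets <- data.frame(id = c("ATP[c]", "ADP[c]", "A[c]"),
                     name = c("ATP", "ADP", "A"), compartment = "c",
                     is_currency = c(TRUE, TRUE, FALSE),
                     category = NA_character_, stringsAsFactors = FALSE)
  stoich <- list(atpase = c("ATP[c]" = -1, "ADP[c]" = 1),
                 other = c("A[c]" = -1, "ATP[c]" = -1, "ADP[c]" = 1))
  rx <- data.frame(id = names(stoich), gene_rule = "",
                   subsystem = NA_character_, lb = 0, ub = 1000,
                   reversible = FALSE, stringsAsFactors = FALSE)
  m <- metabolic_model(mets, rx, stoich)
  g <- build_graph(m)
  expect_false("atpase" %in% igraph::V(g)$name)
  expect_true("other" %in% igraph::V(g)$name)
})

test_that("with no currency list the edge count equals participant count", {
  m <- generate_toy_model(synthetic_scenario(seed = 2))
  g <- build_graph(m, currency = character(0))
  expected <- sum(vapply(m$reactions$id, function(rid) {
    length(unique(names(m$stoichiometry[[rid]])))
  }, numeric(1)))
  expect_equal(igraph::ecount(g), expected)
})

test_that("node scores follow the reporter quantile convention", {
  m <- glutamate_fixture_model()
  g <- build_graph(m)
  rec <- data.frame(metabolite = c("glutamate[c]", "glutamine[c]"),
                    p_reporter = c(0.0062, 0.5), mode = "up",
                    stringsAsFactors = FALSE)
  g <- score_nodes(g, rec)
  sc <- stats::setNames(igraph::V(g)$score, igraph::V(g)$name)
  expect_equal(sc[["glutamate[c]"]], 2.50, tolerance = 1e-3)
  expect_equal(sc[["glutamine[c]"]], 0)
  expect_equal(sc[["NH3[c]"]], 0)          # no record -> null score
  expect_equal(sc[["HMR_3890"]], -0.1)     # reaction penalty
})

test_that("the aggregate score grows as s * sqrt(n) on identical nodes", {
  for (n in c(1, 4, 9)) {
    s <- 1.7
    expect_equal(sum(rep(s, n)) / sqrt(n), s * sqrt(n))
  }
  ## and the search recovers exactly that on a clique of equal scores
  g <- igraph::make_full_graph(5)
  igraph::V(g)$name <- paste0("v", 1:5)
  igraph::V(g)$type <- "metabolite"
  igraph::V(g)$score <- 2
  r <- search_subnetwork(g, iterations = 3000, seed = 5)
  expect_equal(r$score, 2 * sqrt(5))
  expect_setequal(r$selected, igraph::V(g)$name)
})

test_that("a single dominant node is the forced optimum", {
  g <- igraph::make_ring(6)
  igraph::V(g)$name <- paste0("v", 1:6)
  igraph::V(g)$type <- "metabolite"
  igraph::V(g)$score <- c(3, rep(-5, 5))
  r <- search_subnetwork(g, iterations = 2000, seed = 3)
  expect_equal(r$selected, "v1")
  expect_equal(r$score, 3)
})

test_that("annealing reaches the exhaustive optimum on 7-node paths", {
  set.seed(123)
  hits <- 0
  runs <- 10
  g <- igraph::make_ring(7, circular = FALSE)
  igraph::V(g)$name <- paste0("v", 1:7)
  igraph::V(g)$type <- "metabolite"
  scores <- round(stats::runif(7, -2, 3), 2)
  igraph::V(g)$score <- scores
  best <- oracle_subnetwork_optimum(scores)
  for (seed in seq_len(runs)) {
    r <- search_subnetwork(g, iterations = 20000, seed = seed)
    if (abs(r$score - best) < 1e-9) hits <- hits + 1
    expect_gte(r$score, max(scores))  # never worse than best single node
  }
  expect_gte(hits, runs - 1)
})

test_that("search results are seed-deterministic and currency-free", {
  m <- generate_toy_model(synthetic_scenario(seed = 6))
  g <- build_graph(m)
  igraph::V(g)$score <- stats::rnorm(igraph::vcount(g))
  a <- search_subnetwork(g, iterations = 4000, seed = 9)
  b <- search_subnetwork(g, iterations = 4000, seed = 9)
  expect_identical(a[c("selected", "score", "components", "major")],
                   b[c("selected", "score", "components", "major")])
  currency_names <- toupper(default_currency_metabolites)
  expect_false(any(toupper(strip_compartment(a$selected)) %in% currency_names))
})

test_that("export writes GraphML/SIF, honors drop patterns analysis-free", {
  m <- generate_toy_model(synthetic_scenario(seed = 6))
  ex <- generate_expression(m, synthetic_scenario(seed = 6))
  rs <- reporter_scores(m, directional_pvalues(ex$deg, "all"),
                        n_background = 500, seed = 1)
  g <- score_nodes(build_graph(m), rs$records)
  r <- search_subnetwork(g, iterations = 4000, seed = 2)
  dir1 <- withr::local_tempdir()
  paths <- export_subnetwork(r, g, dir1)
  expect_true(all(file.exists(paths)))
  back <- igraph::read_graph(paths[["graphml"]], format = "graphml")
  exported <- union(r$selected, r$bridges)
  expect_setequal(igraph::V(back)$name, exported)
  ## dropping a pattern shrinks the exports but not the component table
  dir2 <- withr::local_tempdir()
  victim <- r$selected[1]
  paths2 <- export_subnetwork(r, g, dir2, drop_patterns = paste0("^",
    gsub("([][+])", "\\\\\\1", victim), "$"))
  back2 <- igraph::read_graph(paths2[["graphml"]], format = "graphml")
  expect_equal(igraph::vcount(back2), igraph::vcount(back) - 1)
  tab1 <- read_tsv_table(paths[["components"]])
  tab2 <- read_tsv_table(paths2[["components"]])
  expect_equal(tab1$node, tab2$node)
})
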