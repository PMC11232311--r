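## small model: two routes from A to B, high-weight direct or low-weight
## detour through X, with a task demanding production of B from A
two_path_model <- function() {
  mets <- data.frame(id = c("A[c]", "B[c]", "X[c]"),
                     name = c("A", "B", "X"), compartment = "c",
                     is_currency = FALSE, category = NA_character_,
                     stringsAsFactors = FALSE)
  stoich <- list(direct = c("A[c]" = -1, "B[c]" = 1),
                 detour1 = c("A[c]" = -1, "X[c]" = 1),
                 detour2 = c("X[c]" = -1, "B[c]" = 1))
  rx <- data.frame(id = names(stoich), gene_rule = "",
                   subsystem = NA_character_, lb = 0, ub = 1000,
                   reversible = FALSE, stringsAsFactors = FALSE)
  metabolic_model(mets, rx, stoich)
}

test_that("extraction keeps only the high-weight path of two alternatives", {
  m <- two_path_model()
  task <- metabolic_task("make_B", c("B[c]" = 0.1), allowed_uptakes = "A[c]")
  w <- c(direct = 5, detour1 = -2, detour2 = -2)
  res <- extract_context_model(m, w, list(task))
  expect_setequal(res$kept, "direct")
  expect_equal(res$objective_milp, 5)
  ## the enumeration oracle agrees
  oracle <- oracle_extraction_optimum(m, w, list(task))
  expect_equal(res$objective_milp, oracle$objective)
})

test_that("with all-positive weights and no tasks everything is kept", {
  m <- chain_model()
  w <- stats::setNames(rep(2, 4), m$reactions$id)
  res <- extract_context_model(m, w, list())
  expect_setequal(res$kept, m$reactions$id)
  expect_equal(res$objective, sum(w))
})

test_that("a task forces a negative-weight reaction into the model", {
  m <- two_path_model()
  task <- metabolic_task("make_B", c("B[c]" = 0.1), allowed_uptakes = "A[c]")
  w <- c(direct = -8, detour1 = -9, detour2 = -9)
  res <- extract_context_model(m, w, list(task))
  expect_true("direct" %in% res$kept)
  expect_equal(res$objective_milp, -8)
  oracle <- oracle_extraction_optimum(m, w, list(task))
  expect_equal(res$objective_milp, oracle$objective)
})

test_that("an infeasible task is reported by name", {
  m <- two_path_model()
  bad <- metabolic_task("impossible", c("A[c]" = 1), allowed_uptakes = character(0))
  expect_error(extract_context_model(m, c(direct = 1), list(bad)),
               "impossible")
})

test_that("branch-and-bound matches enumeration on random instances", {
  for (seed in 1:5) {
    inst <- random_extraction_instance(seed, n_chain = 4, n_extra = 3)
    res <- extract_context_model(inst$model, inst$weights, list(inst$task))
    oracle <- oracle_extraction_optimum(inst$model, inst$weights, list(inst$task))
    expect_equal(res$objective_milp, oracle$objective,
                 info = paste("seed", seed))
    expect_true(all(res$task_report))
  }
})

test_that("shifting all weights by a constant preserves the kept set", {
  inst <- random_extraction_instance(11, n_chain = 4, n_extra = 3)
  res1 <- extract_context_model(inst$model, inst$weights, list(inst$task))
  ## constant +10 makes every weight positive but relative order unchanged;
  ## reactions only enter/leave through the task constraint
  res2 <- extract_context_model(inst$model, inst$weights + 10, list(inst$task))
  expect_true(all(res1$kept %in% res2$kept))
})

test_that("ties break toward the lexicographically smaller reaction id set", {
  mets <- data.frame(id = c("A[c]", "B[c]"), name = c("A", "B"),
                     compartment = "c", is_currency = FALSE,
                     category = NA_character_, stringsAsFactors = FALSE)
  stoich <- list(alpha = c("A[c]" = -1, "B[c]" = 1),
                 beta = c("A[c]" = -1, "B[c]" = 1))
  rx <- data.frame(id = names(stoich), gene_rule = "",
                   subsystem = NA_character_, lb = 0, ub = 1000,
                   reversible = FALSE, stringsAsFactors = FALSE)
  m <- metabolic_model(mets, rx, stoich)
  task <- metabolic_task("t", c("B[c]" = 0.1), allowed_uptakes = "A[c]")
  res <- extract_context_model(m, c(alpha = 3, beta = 3), list(task))
  expect_lte(res$perturbation, 1e-6)
  expect_equal(res$objective_milp, 6)  # both positive duplicates selected
  ## without exchanges neither duplicate carries steady flux; pruning
  ## removes the lighter-id one first, the survivor is task-locked
  expect_equal(res$kept, "beta")
  expect_equal(res$locked, "beta")
  res2 <- extract_context_model(m, c(alpha = 0, beta = 0), list(task))
  expect_equal(res2$kept, "alpha")  # tied at 0: earlier id preferred
})

test_that("gem_signature splits significant sub-model genes by direction", {
  m <- glutamate_fixture_model()
  deg <- data.frame(gene = c("GLUL", "GLS", "SLC25A12", "OTHER"),
                    log2fc = c(0.736, -0.2, 0.5, 2),
                    p = c(1e-8, 0.4, 1e-4, 1e-9),
                    p_adj = c(3.13e-7, 0.5, 5e-3, 1e-8))
  sig <- gem_signature(m, deg, 0.01)
  expect_equal(sig$up, c("GLUL", "SLC25A12"))
  expect_equal(sig$down, character(0))
  expect_equal(gem_signature(m, deg[0, , drop = FALSE]),
               list(up = character(0), down = character(0),
                    zero_fc = character(0)))
  deg$p_adj <- 1e-9; deg$log2fc <- abs(deg$log2fc)
  sig2 <- gem_signature(m, deg, 0.01)
  expect_setequal(sig2$up, intersect(deg$gene, m$genes))
})
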