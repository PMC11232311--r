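test_that("the glutamate fixture parses into the expected model", {
  m <- glutamate_fixture_model()
  expect_equal(nrow(m$reactions), 3)
  expect_setequal(m$genes, c("GLUL", "GLS", "SLC25A12", "SLC25A13"))
  expect_setequal(m$compartments, c("c", "m"))
  st <- m$stoichiometry[["HMR_9802"]]
  expect_equal(st[["H2O[c]"]], -1)
  expect_equal(st[["glutamine[c]"]], -1)
  expect_equal(st[["NH3[c]"]], 1)
  expect_equal(st[["glutamate[c]"]], 1)
})

test_that("equation parsing handles coefficients, reversibility and errors", {
  p <- parse_reaction_equation("2 A[c] + B[m] ⇔ 0.5 C[s]", "r")
  expect_equal(p$stoich, c("A[c]" = -2, "B[m]" = -1, "C[s]" = 0.5))
  expect_true(p$reversible)
  p2 <- parse_reaction_equation("A[s] =>", "ex")
  expect_equal(p2$stoich, c("A[s]" = -1))
  expect_false(p2$reversible)
  ## round trip through the formatter
  p3 <- parse_reaction_equation(format_reaction_equation(p$stoich, TRUE), "r")
  expect_equal(sort(p3$stoich), sort(p$stoich))
  expect_error(parse_reaction_equation("A[c] B[c]", "bad"), "arrow")
  expect_error(parse_reaction_equation("A ⇒ B", "bad"), "malformed")
})

test_that("model validation catches structural errors", {
  mets <- data.frame(id = "A[c]", name = "A", compartment = "c",
                     is_currency = FALSE, category = NA_character_)
  rx <- data.frame(id = "R1", gene_rule = "", subsystem = NA_character_,
                   lb = 0, ub = 10, reversible = FALSE)
  expect_error(metabolic_model(mets, rx, list(R1 = c("B[c]" = 1))),
               "unknown metabolite")
  mets2 <- mets; mets2$compartment <- "m"
  expect_error(metabolic_model(mets2, rx, list(R1 = c("A[c]" = 1))),
               "mismatch")
  rx2 <- rx; rx2$gene_rule <- "G1 AND (G2"
  expect_error(metabolic_model(mets, rx2, list(R1 = c("A[c]" = 1))),
               "unparsable")
  rx3 <- rx; rx3$lb <- -5
  expect_error(metabolic_model(mets, rx3, list(R1 = c("A[c]" = 1))),
               "negative lower bound")
})

test_that("an empty reaction list is a valid model", {
  mets <- data.frame(id = "A[c]", name = "A", compartment = "c",
                     is_currency = FALSE, category = NA_character_)
  m <- metabolic_model(mets, data.frame(), list())
  expect_equal(nrow(m$reactions), 0)
  expect_equal(dim(stoichiometric_matrix(m)), c(1L, 0L))
})

test_that("tabular and SBML round trips are lossless", {
  model <- generate_toy_model(synthetic_scenario(seed = 7))
  for (fmt in c("tabular", "sbml")) {
    path <- if (fmt == "tabular") withr::local_tempdir() else
      withr::local_tempfile(fileext = ".xml")
    write_model(model, path, format = fmt)
    back <- read_model(path, format = fmt)
    expect_setequal(back$metabolites$id, model$metabolites$id)
    expect_setequal(back$reactions$id, model$reactions$id)
    expect_equal(back$genes, model$genes)
    for (rid in model$reactions$id) {
      a <- model$stoichiometry[[rid]]; b <- back$stoichiometry[[rid]]
      expect_equal(b[order(names(b))], a[order(names(a))], info = rid)
    }
    i <- match(model$reactions$id, back$reactions$id)
    expect_equal(back$reactions$lb[i], model$reactions$lb)
    expect_equal(back$reactions$reversible[i], model$reactions$reversible)
    expect_equal(back$metabolites$is_currency[match(model$metabolites$id,
                                                    back$metabolites$id)],
                 model$metabolites$is_currency)
  }
})

test_that("stoichiometric matrix matches an independent re-parse of equations", {
  model <- generate_toy_model(synthetic_scenario(seed = 3))
  dir <- withr::local_tempdir()
  write_model(model, dir)
  rxns <- read_tsv_table(file.path(dir, "reactions.tsv"))
  S <- as.matrix(stoichiometric_matrix(model, sparse = FALSE))
  expect_equal(dim(S), c(nrow(model$metabolites), nrow(model$reactions)))
  for (i in seq_len(nrow(rxns))) {
    st <- parse_reaction_equation(rxns$equation[i], rxns$id[i])$stoich
    col <- S[, rxns$id[i]]
    expect_equal(sum(col), sum(st), info = rxns$id[i])
    expect_equal(sort(names(col[col != 0])), sort(names(st)))
    expect_equal(unname(col[names(st)]), unname(st))
  }
  ## column of the glutamine-synthesis fixture reaction
  g <- glutamate_fixture_model()
  colg <- stoichiometric_matrix(g)[, "HMR_3890"]
  expect_equal(colg[["glutamate[c]"]], -1)
  expect_equal(colg[["glutamine[c]"]], 1)
})

test_that("flux consistency finds forced chains and excludes dead ends", {
  m <- chain_model()
  expect_setequal(flux_consistent_reactions(m), m$reactions$id)
  ## add a dead-end branch producing D with no consumer
  mets <- rbind(m$metabolites,
                data.frame(id = "D[c]", name = "D", compartment = "c",
                           is_currency = FALSE, category = NA_character_))
  st <- c(m$stoichiometry, list(R3 = c("A[c]" = -1, "D[c]" = 1)))
  rx <- rbind(m$reactions,
              data.frame(id = "R3", gene_rule = "", subsystem = NA_character_,
                         lb = 0, ub = 1000, reversible = FALSE))
  m2 <- metabolic_model(mets, rx, st)
  expect_setequal(flux_consistent_reactions(m2), m$reactions$id)
})

test_that("flux consistency agrees with the reachability oracle on random networks", {
  for (seed in 1:8) {
    inst <- random_extraction_instance(seed, n_chain = 5, n_extra = 10)
    model <- inst$model
    ## open exchanges at both chain ends so something can flow
    mets <- model$metabolites
    st <- c(model$stoichiometry,
            list(EX_in = c("m1[c]" = 1),
                 EX_out = stats::setNames(-1, sprintf("m%d[c]", 5))))
    rx <- rbind(model$reactions,
                data.frame(id = c("EX_in", "EX_out"), gene_rule = "",
                           subsystem = NA_character_, lb = 0, ub = 1000,
                           reversible = FALSE))
    model <- metabolic_model(mets, rx, st)
    got <- flux_consistent_reactions(model, 1e-4)
    expect_setequal(got, oracle_flux_consistent(model))
  }
})

test_that("flux-consistent set is monotone under bound relaxation", {
  model <- generate_toy_model(synthetic_scenario(seed = 5))
  narrow <- model
  narrow$reactions$ub <- pmin(narrow$reactions$ub, 10)
  narrow$reactions$lb <- pmax(narrow$reactions$lb, -10)
  set_narrow <- flux_consistent_reactions(narrow)
  set_wide <- flux_consistent_reactions(model)
  expect_true(all(set_narrow %in% set_wide))
})
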