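test_that("gene rules parse and evaluate with OR=max, AND=min", {
  sc <- c(A = 5, B = -8, C = 1)
  expect_equal(evaluate_gene_rule("A", sc), 5)
  expect_equal(evaluate_gene_rule("(A AND B) OR C", sc), max(min(5, -8), 1))
  expect_equal(evaluate_gene_rule("(A AND B) OR C", sc), 1)
  expect_equal(evaluate_gene_rule("A and B Or C", sc), 1)  # keyword case-insensitive
  expect_equal(evaluate_gene_rule("", sc), 0)
  expect_equal(evaluate_gene_rule("A AND UNKNOWN", sc, default = -8), -8)
  expect_setequal(rule_genes("(A AND B) OR C OR A"), c("A", "B", "C"))
  expect_error(parse_gene_rule("A AND"), "unparsable")
  expect_error(parse_gene_rule("A !! B"), "unparsable")
})

## hand-built 4 genes x 5 samples matrix; the 20 pooled values, sorted,
## put 1.4/2.2 at positions 5/6 (so the type-7 lower quartile interpolates
## to exactly 2) and 8/8 at positions 15/16 (upper quartile exactly 8)
quartile_fixture <- function() {
  rbind(g1 = c(1, 1.1, 1.2, 1.3, 1.4),     # all < 2       -> ABSENT
        g2 = c(2.2, 3.5, 9, 5.0, 2.4),     # max 9 > 8     -> HIGH
        g3 = c(2.6, 6.0, 8, 4.0, 2.8),     # max exactly 8 -> MEDIUM
        g4 = c(3.0, 8, 8.5, 9.5, 10))      # max 10        -> HIGH
}

test_that("classify_genes applies pooled quartiles and the strict ABSENT rule", {
  m <- quartile_fixture()
  q <- stats::quantile(as.vector(m), c(0.25, 0.75), type = 7, names = FALSE)
  expect_equal(q, c(2, 8))  # fixture is built to pin the pooled quartiles
  cl <- classify_genes(m)
  tiers <- stats::setNames(cl$tier, cl$gene)
  expect_equal(tiers[["g1"]], "ABSENT")  # below Q1 in 100% of samples
  expect_equal(tiers[["g2"]], "HIGH")    # max 9 > Q3
  expect_equal(tiers[["g3"]], "MEDIUM")  # max exactly Q3 -> not HIGH
  expect_equal(tiers[["g4"]], "HIGH")
  expect_setequal(cl$gene, rownames(m))  # tiers partition the gene set
})

test_that("a gene constant at exactly Q1 is LOW, not ABSENT", {
  ## pooled sorted values 0,2,2,2,2,4,6,10: type-7 Q1 is exactly 2
  m <- rbind(ga = c(2, 2, 2, 2), gb = c(0, 4, 6, 10))
  q1 <- stats::quantile(as.vector(m), 0.25, type = 7, names = FALSE)
  expect_equal(q1, 2)
  cl <- classify_genes(m)
  tiers <- stats::setNames(cl$tier, cl$gene)
  expect_equal(tiers[["ga"]], "LOW")   # never strictly below Q1; max <= Q1
  expect_equal(tiers[["gb"]], "HIGH")
})

test_that("all genes above Q3 are HIGH and degenerate matrices error", {
  m <- matrix(seq(1, 24), nrow = 4,
              dimnames = list(paste0("g", 1:4), NULL))
  ## every gene's max falls in the pooled top quartile
  cl <- classify_genes(m)
  expect_true(all(cl$tier == "HIGH"))
  expect_error(classify_genes(matrix(1, 3, 4, dimnames = list(letters[1:3], NULL))),
               "degenerate")
})

test_that("classification is invariant to sample order", {
  set.seed(42)
  m <- matrix(rnorm(200, 8, 2), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), NULL))
  cl1 <- classify_genes(m)
  cl2 <- classify_genes(m[, sample(10)])
  expect_equal(cl1, cl2, ignore_attr = TRUE)
})

test_that("roughly a quarter of pooled iid values fall below Q1", {
  set.seed(7)
  m <- matrix(rnorm(5000), 100, 50, dimnames = list(sprintf("g%03d", 1:100), NULL))
  q1 <- attr(classify_genes(m), "q1")
  frac <- mean(as.vector(m) < q1)
  se <- sqrt(0.25 * 0.75 / 5000)
  expect_lt(abs(frac - 0.25), 3 * se + 1 / 5000)
})

test_that("force_high applies DEG and protein evidence and is idempotent", {
  cl <- data.frame(gene = c("A", "B", "C"), tier = c("ABSENT", "LOW", "HIGH"),
                   provenance = "quartile", stringsAsFactors = FALSE)
  deg <- data.frame(gene = "A", log2fc = 1, p = 1e-6, p_adj = 1e-5)
  out <- force_high(cl, deg, p_adj_force = 1e-3, proteins = "D", quiet = TRUE)
  expect_equal(out$tier[out$gene == "A"], "HIGH")
  expect_equal(out$provenance[out$gene == "A"], "forced_deg")
  expect_equal(out$tier[out$gene == "D"], "HIGH")  # added from proteins
  expect_equal(out$provenance[out$gene == "D"], "forced_protein")
  expect_equal(out$tier[out$gene == "B"], "LOW")   # untouched
  again <- force_high(out, deg, p_adj_force = 1e-3, proteins = "D", quiet = TRUE)
  expect_equal(again, out, ignore_attr = TRUE)
  ## empty evidence leaves classes unchanged
  expect_equal(force_high(cl, NULL, proteins = NULL), cl, ignore_attr = TRUE)
})

test_that("cohorts combine by tier maximum without averaging", {
  a <- data.frame(gene = c("x", "y", "z"), tier = c("LOW", "ABSENT", "HIGH"),
                  provenance = "quartile", stringsAsFactors = FALSE)
  b <- data.frame(gene = c("x", "y", "w"), tier = c("MEDIUM", "ABSENT", "LOW"),
                  provenance = "quartile", stringsAsFactors = FALSE)
  cc <- combine_classes(a, b)
  tiers <- stats::setNames(cc$tier, cc$gene)
  expect_equal(tiers[["x"]], "MEDIUM")
  expect_equal(tiers[["y"]], "ABSENT")
  expect_equal(tiers[["z"]], "HIGH")
  expect_equal(tiers[["w"]], "LOW")
})

test_that("reaction weights evaluate rules over tier scores", {
  m <- glutamate_fixture_model()
  cl <- data.frame(gene = c("GLUL", "GLS", "SLC25A12"),
                   tier = c("HIGH", "ABSENT", "MEDIUM"),
                   provenance = "quartile", stringsAsFactors = FALSE)
  w <- reaction_weights(m, cl)
  expect_equal(w[["HMR_3890"]], 5)    # single HIGH gene
  expect_equal(w[["HMR_9802"]], -8)   # single ABSENT gene
  ## OR rule: max(MEDIUM, missing-> ABSENT) = 1
  expect_equal(w[["HMR_3825"]], 1)
  ## empty rule -> 0
  m2 <- chain_model()
  w2 <- reaction_weights(m2, cl)
  expect_equal(w2[["EX_A"]], 0)
})
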