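make_mm <- function(ab, batch, type, group) {
  metabolomics_matrix(ab, data.frame(sample = colnames(ab), batch = batch,
                                     sample_type = type, group = group,
                                     stringsAsFactors = FALSE))
}

test_that("qc_filter applies the missingness and RSD rules", {
  ab <- rbind(
    m_miss = c(NA, NA, NA, 4, 5, 6, 7, 8, 9, 10),       # 30% missing
    m_flat = c(10, 10, 10, 5, 6, 7, 8, 9, 10, 11),       # QC RSD 0
    m_noisy = c(10, 30, 2, 5, 6, 7, 8, 9, 10, 11),       # QC RSD >> 0.5
    m_ok = c(10, 11, 9, 5, 6, 7, 8, 9, 10, 11))
  colnames(ab) <- sprintf("s%02d", 1:10)
  m <- make_mm(ab, batch = "B1",
               type = rep(c("QC", "primary"), c(3, 7)),
               group = rep(c("none", "IPH-", "IPH+"), c(3, 3, 4)))
  res <- qc_filter(m)
  expect_setequal(rownames(res$matrix$abundance), c("m_flat", "m_ok"))
  expect_equal(res$excluded$rule[res$excluded$metabolite == "m_miss"],
               "missingness")
  expect_equal(res$excluded$rule[res$excluded$metabolite == "m_noisy"], "rsd")
  ## hand computation of the noisy RSD
  qc <- c(10, 30, 2)
  expect_equal(res$excluded$value[res$excluded$metabolite == "m_noisy"],
               stats::sd(qc) / mean(qc))
  ## rules commute: filtering is a pure predicate per metabolite
  res2 <- qc_filter(res$matrix)
  expect_equal(rownames(res2$matrix$abundance), rownames(res$matrix$abundance))
})

test_that("qc_filter without QC samples warns and skips the RSD rule", {
  ab <- rbind(a = c(1, 2, 3, 4, 5, 6))
  colnames(ab) <- sprintf("s%d", 1:6)
  m <- make_mm(ab, "B1", "primary", rep(c("IPH-", "IPH+"), 3))
  expect_warning(res <- qc_filter(m), "RSD rule skipped")
  expect_equal(nrow(res$matrix$abundance), 1)
})

test_that("batch correction synchronizes QC medians exactly", {
  ## two batches with QC medians 10 and 20 -> global 15, factors 1.5 / 0.75
  ab <- rbind(met = c(10, 20, 8, 30))
  colnames(ab) <- c("q1", "q2", "p1", "p2")
  m <- make_mm(ab, batch = c("B1", "B2", "B1", "B2"),
               type = c("QC", "QC", "primary", "primary"),
               group = c("none", "none", "IPH-", "IPH+"))
  out <- batch_correct(m)$matrix
  expect_equal(unname(out$abundance["met", ]), c(15, 15, 12, 22.5))
  ## idempotence
  out2 <- batch_correct(out)$matrix
  expect_equal(out2$abundance, out$abundance)
  ## single batch is identity
  ms <- make_mm(ab, batch = "B1", type = c("QC", "QC", "primary", "primary"),
                group = c("none", "none", "IPH-", "IPH+"))
  expect_equal(batch_correct(ms)$matrix$abundance, ab)
})

test_that("batch QC median of zero flags and leaves values uncorrected", {
  ab <- rbind(met = c(0, 20, 8, 30))
  colnames(ab) <- c("q1", "q2", "p1", "p2")
  m <- make_mm(ab, batch = c("B1", "B2", "B1", "B2"),
               type = c("QC", "QC", "primary", "primary"),
               group = c("none", "none", "IPH-", "IPH+"))
  res <- batch_correct(m)
  expect_equal(nrow(res$flagged), 1)
  expect_equal(res$matrix$abundance["met", "p1"], 8)  # B1 untouched
})

test_that("the exact Wilcoxon branch matches full label enumeration", {
  ## {1,2,3} vs {4,5,6}: the rank-sum extreme, two-sided p = 2/20 = 0.1
  expect_equal(oracle_wilcoxon_p(1:3, 4:6), 0.1)
  expect_equal(stats::wilcox.test(1:3, 4:6)$p.value, 0.1)
  ## a non-extreme case agrees too
  x <- c(1, 4, 5); y <- c(2, 3, 6)
  expect_equal(stats::wilcox.test(x, y)$p.value, oracle_wilcoxon_p(x, y))
})

test_that("differential abundance calls planted shifts and skips degenerates", {
  set.seed(11)
  n <- 13
  ab <- rbind(
    shifted = c(exp(rnorm(n, log(100), 0.1)), exp(rnorm(n, log(200), 0.1))),
    flat = c(exp(rnorm(n, log(50), 0.1)), exp(rnorm(n, log(50), 0.1))),
    constant = rep(5, 2 * n))
  colnames(ab) <- sprintf("s%02d", seq_len(2 * n))
  m <- make_mm(ab, "B1", "primary", rep(c("IPH-", "IPH+"), each = n))
  calls <- differential_abundance(m, case = "IPH+", control = "IPH-")
  expect_equal(calls$call[calls$metabolite == "shifted"], "up")
  expect_equal(calls$call[calls$metabolite == "flat"], "unchanged")
  expect_equal(calls$call[calls$metabolite == "constant"], "unchanged")
  expect_equal(calls$p[calls$metabolite == "constant"], 1)
  ## label-symmetric data stays unchanged
  sym <- rbind(s = rep(c(1, 2, 3, 4, 5, 6), 2))
  colnames(sym) <- sprintf("t%02d", 1:12)
  msym <- make_mm(sym, "B1", "primary", rep(c("IPH-", "IPH+"), 6))
  csym <- differential_abundance(msym, case = "IPH+", control = "IPH-")
  expect_equal(csym$call, "unchanged")
})

test_that("BH adjustment agrees with a literal step-up", {
  set.seed(5)
  p <- runif(40)
  expect_equal(stats::p.adjust(p, "BH"), oracle_bh(p))
})

test_that("permutation p matches the hypergeometric tail within Monte Carlo error", {
  set.seed(2)
  mets <- sprintf("M%03d", 1:60)
  calls <- data.frame(metabolite = mets,
                      call = sample(rep(c("up", "unchanged"), c(18, 42))),
                      stringsAsFactors = FALSE)
  categories <- stats::setNames(rep(c("lipid", "other"), c(15, 45)), mets)
  n_perm <- 20000
  res <- category_permutation_test(calls, categories, "up",
                                   n_perm = n_perm, seed = 3)
  row <- res[res$category == "lipid", ]
  obs <- row$n_dysregulated_in_category
  p_hyper <- stats::phyper(obs - 1, 18, 42, 15, lower.tail = FALSE)
  se <- sqrt(p_hyper * (1 - p_hyper) / n_perm)
  expect_lt(abs(row$p_perm_over - p_hyper), 3 * se + 2 / n_perm)
})

test_that("the whole-panel category cannot be over-represented", {
  mets <- sprintf("M%02d", 1:20)
  calls <- data.frame(metabolite = mets,
                      call = rep(c("up", "unchanged"), 10),
                      stringsAsFactors = FALSE)
  categories <- stats::setNames(rep("all", 20), mets)
  res <- category_permutation_test(calls, categories, "up",
                                   n_perm = 500, seed = 1)
  expect_equal(res$p_perm_over, 1)
})

test_that("permutation results are seed-deterministic", {
  mets <- sprintf("M%02d", 1:30)
  calls <- data.frame(metabolite = mets,
                      call = sample(rep(c("down", "unchanged"), c(8, 22))),
                      stringsAsFactors = FALSE)
  categories <- stats::setNames(rep(c("a", "b", "c"), 10), mets)
  r1 <- category_permutation_test(calls, categories, "down", 2000, seed = 9)
  r2 <- category_permutation_test(calls, categories, "down", 2000, seed = 9)
  expect_identical(r1, r2)
})

test_that("metabolomics TSV dialect round-trips", {
  gen <- generate_metabolomics(generate_toy_model(synthetic_scenario(8)),
                               synthetic_scenario(8))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_metabolomics(gen$matrix, path)
  back <- read_metabolomics(path)
  expect_equal(back$samples, gen$matrix$samples)
  expect_equal(back$abundance, gen$matrix$abundance, tolerance = 1e-12)
})
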