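test_that("tag-positive selection keeps exactly the cells with nonzero tag counts", {
  counts <- matrix(c(0L, 1L, 0L, 2L,
                     0L, 0L, 3L, 1L,
                     5L, 5L, 5L, 5L), nrow = 3, byrow = TRUE)
  x <- count_matrix(counts, gene_ids = c("Dendra2", "HaloTag", "G1"),
                    barcodes = sprintf("BC%d", 1:4),
                    tag_genes = c("Dendra2", "HaloTag"))
  expect_identical(select_tag_positive_cells(x, c("Dendra2", "HaloTag")),
                   c("BC2", "BC3", "BC4"))
  expect_identical(select_tag_positive_cells(x, "Dendra2"), c("BC2", "BC4"))
  expect_error(select_tag_positive_cells(x, "GFP"), "GFP")
})

test_that("tag-positive fraction tracks the generator's detection rate", {
  cfg <- study_config(n_samples = 1, cells_per_sample = 1000, n_genes = 30,
                      tag_detection_rate = 0.08, tag_genes = "Dendra2",
                      frac_damaged_cells = 0, seed = 91)
  st <- generate_study(cfg)
  frac <- length(select_tag_positive_cells(st$matrix, "Dendra2")) / 1000
  expect_lt(abs(frac - 0.08), 3 * sqrt(0.08 * 0.92 / 1000) + 0.005)
})

test_that("tag correlation reproduces perfect correlation and drops degenerate genes", {
  set.seed(92)
  tag <- rpois(200, 3)
  m <- rbind(TAG = tag, SAME = tag, NOISE = rpois(200, 2),
             ALLZERO = 0, CONST = 0)
  m["CONST", 1:200] <- 0  # expressed nowhere: removed, not dropped
  norm <- Matrix::Matrix(log1p(m), sparse = TRUE)
  res <- tag_correlation(norm, "TAG")
  expect_equal(res$r[res$gene == "SAME"], 1)
  expect_false("ALLZERO" %in% res$gene)
  expect_false("CONST" %in% res$gene)

  # an expressed gene without variance is dropped with a reason
  m2 <- rbind(TAG = tag, FLAT = 1L)
  res2 <- tag_correlation(Matrix::Matrix(log1p(m2), sparse = TRUE), "TAG")
  expect_identical(attr(res2, "dropped"), "FLAT")

  # a tag without variance is a degenerate input
  m3 <- rbind(TAG = 0L, G = rpois(200, 1))
  expect_error(tag_correlation(Matrix::Matrix(log1p(m3), sparse = TRUE), "TAG"),
               "variance")
})

test_that("correlation p and q values match cor.test and the BH oracle", {
  set.seed(93)
  n <- 60
  tag <- rnorm(n)
  m <- rbind(TAG = tag,
             A = 0.6 * tag + rnorm(n), B = rnorm(n), C = -0.4 * tag + rnorm(n))
  norm <- Matrix::Matrix(m, sparse = TRUE)
  res <- tag_correlation(norm, "TAG")
  for (g in c("A", "B", "C")) {
    ct <- cor.test(m[g, ], tag)
    row <- res[res$gene == g, ]
    expect_equal(row$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(row$p, ct$p.value, tolerance = 1e-10)
  }
  expect_equal(res$q, oracle_bh(res$p), tolerance = 1e-12)
})

test_that("BH step-up agrees with brute force on random p vectors", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), method = "BH"),
               c(0.03, 0.03, 0.04))
  set.seed(94)
  for (rep in 1:10) {
    p <- runif(sample(3:100, 1))
    expect_equal(p.adjust(p, method = "BH"), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("planted tag-covarying genes are recovered by the correlation screen", {
  counts <- latent_factor_counts(n_planted = 50, n_null = 500,
                                 n_cells = 2000, loading = 0.5, seed = 95)
  x <- count_matrix(counts, gene_ids = rownames(counts),
                    barcodes = sprintf("BC%04d", seq_len(ncol(counts))),
                    tag_genes = "TAG")
  res <- tag_correlation(normalize_counts(x), "TAG")
  planted <- grepl("^PLANT", res$gene)
  recall <- mean(res$significant[planted])
  expect_gte(recall, 0.9)
  fpr <- mean(res$significant[grepl("^NULL", res$gene)])
  expect_lt(fpr, 0.1)
})

test_that("differential expression computes fold changes, floors p, and calls hits", {
  # de-logged group means 2 vs 1 -> log2fc ~ 1
  a_val <- log1p(2); b_val <- log1p(1)
  norm <- Matrix::Matrix(rbind(G1 = c(rep(a_val, 30), rep(b_val, 30)),
                               G2 = rep(1, 60)), sparse = TRUE)
  colnames(norm) <- sprintf("BC%d", 1:60)
  de <- differential_expression(norm, sprintf("BC%d", 1:30),
                                sprintf("BC%d", 31:60))
  expect_equal(de$log2fc[de$gene == "G1"], 1, tolerance = 1e-6)
  expect_equal(de$direction[de$gene == "G1"], "up")
  # identical constant groups: no change, no significance
  expect_equal(de$log2fc[de$gene == "G2"], 0)
  expect_equal(de$p[de$gene == "G2"], 1)
  expect_false(any(de$significant[de$gene == "G2"]))
  # every reported p respects the floor
  expect_true(all(de$p >= 2.225074e-308))
  expect_equal(de$p_adj, pmin(1, 2 * de$p))  # Bonferroni over 2 genes

  expect_error(differential_expression(norm, character(0), "BC1"), "nonempty")
  expect_error(differential_expression(norm, "BC1", "BC1"), "disjoint")
})

test_that("underflowing p values are clamped to the printed minimum", {
  set.seed(96)
  # huge separation so the normal-approximation p underflows to 0
  norm <- Matrix::Matrix(rbind(G = c(rnorm(3000, 1, 0.01),
                                     rnorm(3000, 10, 0.01))), sparse = TRUE)
  rownames(norm) <- "G"
  colnames(norm) <- sprintf("BC%d", 1:6000)
  de <- differential_expression(norm, sprintf("BC%d", 1:3000),
                                sprintf("BC%d", 3001:6000))
  expect_equal(de$p, 2.225074e-308)
})

test_that("planted 2-fold shifts are recovered with no false positives", {
  set.seed(97)
  n_cells <- 500
  mu <- runif(1050, 0.5, 5)
  a <- vapply(seq_len(1050), function(g) {
    f <- if (g <= 50) 2 else 1
    rnbinom(n_cells, size = 2, mu = f * mu[g])
  }, numeric(n_cells))
  b <- vapply(seq_len(1050), function(g) rnbinom(n_cells, size = 2, mu = mu[g]),
              numeric(n_cells))
  counts <- cbind(t(a), t(b))
  rownames(counts) <- c(sprintf("DE%03d", 1:50), sprintf("NULL%04d", 1:1000))
  x <- count_matrix(counts, gene_ids = rownames(counts),
                    barcodes = sprintf("BC%04d", seq_len(2 * n_cells)))
  norm <- normalize_counts(x)
  de <- differential_expression(norm, sprintf("BC%04d", 1:n_cells),
                                sprintf("BC%04d", (n_cells + 1):(2 * n_cells)))
  hits <- de$gene[de$significant]
  expect_gte(sum(grepl("^DE", hits)), 50 * 0.95)
  expect_lte(sum(grepl("^NULL", hits)), 1)
})

test_that("Fisher enrichment matches hypergeometric enumeration and edge cases", {
  enr <- llps_enrichment(c("a", "b"), c("a", "b"), c("a", "b", "c", "d"))
  expect_equal(enr$table, matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE,
                                 dimnames = dimnames(enr$table)))
  expect_equal(enr$p, 1 / 3, tolerance = 1e-12)
  expect_true(is.finite(enr$odds_ratio))  # Haldane-corrected with zero cells

  # set = universe carries no information
  expect_equal(llps_enrichment(c("a"), letters[1:4], letters[1:4])$p, 1)
  # empty significant set
  expect_equal(llps_enrichment(character(0), c("a"), letters[1:4])$p, 1)
  expect_error(llps_enrichment("a", "a", character(0)), "empty universe")
  # Bonferroni across contrasts
  enr3 <- llps_enrichment(c("a", "b"), c("a", "b"), letters[1:4],
                          n_contrasts = 3)
  expect_equal(enr3$p_adj, min(1, 3 * enr3$p))
})

test_that("Fisher p agrees with full enumeration for all margins up to 12", {
  set.seed(98)
  for (rep in 1:40) {
    a <- sample(0:6, 1); b <- sample(0:6, 1)
    cc <- sample(0:6, 1); d <- sample(0:6, 1)
    if (a + b == 0 || cc + d == 0 || a + cc == 0 || b + d == 0) next
    tab <- matrix(c(a, b, cc, d), 2, 2, byrow = TRUE)
    expect_equal(fisher.test(tab)$p.value, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})
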