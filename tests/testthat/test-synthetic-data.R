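test_that("NB sampler matches its closed-form moments", {
  n <- 5e4
  for (par in list(c(mu = 10, kon = 2), c(mu = 1, kon = 0.5),
                   c(mu = 0.3, kon = 5))) {
    x <- sample_nb_counts(par["mu"], par["kon"], n, seed = 11)
    mu <- par["mu"]; kon <- par["kon"]
    v <- mu * (1 + mu / kon)
    se_mean <- sqrt(v / n)
    expect_lt(abs(mean(x) - mu), 3 * se_mean)
    cv2_true <- 1 / mu + 1 / kon
    cv2_hat <- var(x) / mean(x)^2
    # generous Monte-Carlo band for the variance-based statistic
    expect_lt(abs(cv2_hat - cv2_true), 0.15 * cv2_true)
  }
})

test_that("NB sampler approaches the Poisson limit for large kon", {
  x <- sample_nb_counts(1, 1e9, 5e4, seed = 2)   # kon capped at 1e6
  cv2 <- var(x) / mean(x)^2
  expect_lt(abs(cv2 - 1), 0.05)                  # CV^2 -> 1/mu = 1
  expect_lt(abs(mean(x) - 1), 0.02)
})

test_that("NB zero fraction follows (1/(1+b))^kon", {
  x <- sample_nb_counts(1, 1, 5e4, seed = 3)
  expect_lt(abs(mean(x == 0) - 0.5), 0.01)
})

test_that("NB sampler rejects nonpositive parameters and is reproducible", {
  expect_error(sample_nb_counts(0, 1, 10), "positive")
  expect_error(sample_nb_counts(1, -2, 10), "positive")
  expect_identical(sample_nb_counts(5, 1, 100, seed = 9),
                   sample_nb_counts(5, 1, 100, seed = 9))
})

test_that("telegraph simulator honours degenerate limits", {
  p0 <- telegraph_params(k_on = 1, k_off = 1, alpha = 0)
  expect_true(all(simulate_telegraph(p0, 50, seed = 1) == 0))

  # constitutive limit: promoter essentially always on -> Poisson(alpha/d)
  pc <- telegraph_params(k_on = 500, k_off = 0.001, alpha = 5)
  x <- simulate_telegraph(pc, 3000, seed = 2)
  expect_lt(abs(mean(x) - 5), 0.2)
  expect_lt(abs(var(x) / mean(x) - 1), 0.15)     # Fano factor ~ 1
})

test_that("telegraph stationary law matches the NB approximation in the burst limit", {
  p <- telegraph_params(k_on = 0.5, k_off = 50, alpha = 250)  # b = 5, mu = 2.5
  x <- simulate_telegraph(p, 8000, seed = 4)
  expect_lt(tv_vs_nb(x, mu = 2.5, kon = 0.5), 0.05)
})

test_that("telegraph simulator validates burn-in", {
  p <- telegraph_params(1, 1, 1)
  expect_error(simulate_telegraph(p, 10, burn_in_time = 0), "burn_in")
})

test_that("generate_study bookkeeping: dimensions, damaged cells, truth table", {
  cfg <- study_config(n_samples = 2, cells_per_sample = 100, n_genes = 50,
                      frac_damaged_cells = 0.1, seed = 5)
  st <- generate_study(cfg)
  expect_equal(ncol(st$matrix$counts), 200)
  expect_equal(sum(st$cell_truth$damaged), 20)
  expect_equal(unname(table(st$cell_truth$sample[st$cell_truth$damaged])),
               c(10L, 10L), ignore_attr = TRUE)
  expect_equal(nrow(st$truth), 50 * 2)
  # GroundTruth self-consistency: burst size is exactly mu/kon
  expect_identical(st$truth$burst_size_true,
                   st$truth$mu_true / st$truth$kon_true)
  expect_equal(st$truth$burst_size_true * st$truth$kon_true, st$truth$mu_true)
})

test_that("burst-size effect scales the true mean and leaves kon alone", {
  cfg <- study_config(n_samples = 2, cells_per_sample = 20, n_genes = 30,
                      effects = list(list(sample = 2, parameter = "burst_size",
                                          factor = 1.5)),
                      seed = 6)
  st <- generate_study(cfg)
  a <- st$truth[st$truth$sample == "S1", ]
  b <- st$truth[st$truth$sample == "S2", ]
  expect_equal(b$mu_true, 1.5 * a$mu_true)
  expect_equal(b$kon_true, a$kon_true)
  expect_equal(b$burst_size_true, 1.5 * a$burst_size_true)
})

test_that("effect specs referencing unknown genes or samples are rejected", {
  expect_error(study_config(n_samples = 2, n_genes = 10,
                            effects = list(list(sample = 3, factor = 2))),
               "out of range")
  expect_error(study_config(n_samples = 2, n_genes = 10,
                            effects = list(list(sample = 1, genes = 11,
                                                factor = 2))),
               "out of range")
})

test_that("tag genes hit the configured detection rate", {
  cfg <- study_config(n_samples = 2, cells_per_sample = 1000, n_genes = 30,
                      tag_detection_rate = 0.08, frac_damaged_cells = 0,
                      seed = 7)
  st <- generate_study(cfg)
  for (tag in c("Dendra2", "HaloTag")) {
    row <- st$matrix$counts[match(tag, st$matrix$gene_ids), ]
    grp <- st$matrix$sample == c(Dendra2 = "S1", HaloTag = "S2")[tag]
    nonzero <- sum(row[grp] > 0)
    # binomial tolerance: 1000 draws at 0.08 -> about 80 +/- 3 sd
    expect_lt(abs(nonzero - 80), 3 * sqrt(1000 * 0.08 * 0.92) + 3)
    expect_equal(sum(row[!grp] > 0), 0)  # expressed only in its group
  }
})

test_that("identical seeds reproduce the study bit-for-bit", {
  cfg <- study_config(n_samples = 2, cells_per_sample = 50, n_genes = 20,
                      seed = 8)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(as.matrix(s1$matrix$counts), as.matrix(s2$matrix$counts))
  expect_identical(s1$truth, s2$truth)
})

test_that("study config validates fractions and ranges", {
  expect_error(study_config(frac_damaged_cells = 1.2), "\\[0, 1\\]")
  expect_error(study_config(mu_range = c(5, 1)), "ordered")
  expect_error(study_config(kon_range = c(-1, 2)), "ordered|positive")
})
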