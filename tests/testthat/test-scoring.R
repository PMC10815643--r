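test_that("K2 score matches exact factorial evaluation on worked examples", {
  # rows are joint genotypes, columns the two phenotype classes
  expect_equal(k2_score(rbind(c(3, 1), c(0, 4))), -log(0.01), tolerance = 1e-10)
  expect_equal(k2_score(rbind(c(1, 0))), log(2), tolerance = 1e-12)
})

test_that("exp(-k2_score) equals the exact K2 product for random small tables", {
  set.seed(101)
  for (i in 1:60) {
    m <- random_small_table(sample(c(2L, 9L), 1L))
    expect_equal(exp(-k2_score(m)), exact_k2_product(m),
                 tolerance = 1e-9)
  }
})

test_that("K2 score is invariant to row order and empty rows", {
  set.seed(102)
  m <- random_small_table(5L)
  expect_identical(k2_score(m), k2_score(m[sample(nrow(m)), ]))
  expect_equal(k2_score(rbind(m, c(0, 0))), k2_score(m))
})

test_that("expected counts reproduce margins", {
  expect_equal(expected_counts(rbind(c(30, 10), c(10, 30))),
               matrix(20, 2, 2))
  expect_equal(expected_counts(rbind(c(4, 0))), cbind(4, 0))
  set.seed(103)
  for (i in 1:20) {
    m <- random_small_table(4L)
    E <- expected_counts(m)
    expect_equal(rowSums(E), rowSums(m))
    expect_equal(colSums(E), colSums(m))
  }
})

test_that("likelihood-ratio statistic matches hand computation and null case", {
  expect_identical(lr_score(matrix(20, 2, 2)), 0)
  g <- 2 * (2 * 30 * log(1.5) + 2 * 10 * log(0.5))
  expect_equal(lr_score(rbind(c(30, 10), c(10, 30))), g, tolerance = 1e-10)
  expect_equal(g, 20.93, tolerance = 1e-3)
})

test_that("G is non-negative and zero only at the independence expectation", {
  set.seed(104)
  for (i in 1:30) {
    m <- random_small_table(4L)
    g <- lr_score(m)
    expect_gte(g, 0)
    if (g < 1e-12) expect_equal(unname(m + 0), expected_counts(m))
  }
  # proportional rows achieve the expectation exactly
  expect_equal(lr_score(rbind(c(10, 20), c(5, 10))), 0, tolerance = 1e-12)
})

test_that("Pearson chi-square matches the closed-form example", {
  r <- pearson_chi2(rbind(c(30, 10), c(10, 30)))
  expect_equal(r$statistic, 20)
  expect_identical(r$df, 1L)
  expect_equal(r$p, 7.744216e-06, tolerance = 1e-4)
  null <- pearson_chi2(matrix(20, 2, 2))
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)
})

test_that("chi-square and G agree asymptotically on well-filled tables", {
  set.seed(105)
  for (i in 1:20) {
    m <- matrix(sample(60:120, 4L, replace = TRUE), 2, 2)
    x2 <- pearson_chi2(m)$statistic
    g <- lr_score(m)
    if (g > 0.5) expect_lt(abs(x2 - g) / g, 0.10)
  }
})

test_that("g_test reuses the LR statistic and p is monotone in G", {
  set.seed(106)
  for (i in 1:10) {
    m <- random_small_table(3L)
    gt <- g_test(m)
    expect_identical(gt$statistic, lr_score(m))
  }
  p <- stats::pchisq(c(1, 5, 20), 1, lower.tail = FALSE)
  expect_true(all(diff(p) < 0))
  expect_warning(g_test(rbind(c(3, 4))), "df")
})

test_that("contingency tables count joint genotypes correctly", {
  ct <- build_contingency(toy_dataset(), c(1L, 2L))
  expect_identical(ct$row_labels, c("0/0", "1/2"))
  expect_identical(ct$counts, matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                     dimnames = list(NULL, c("control", "case"))))
  expect_error(build_contingency(toy_dataset(), c(1L, 1L)), "distinct")
})

test_that("contingency row sums equal a naive recount for random panels", {
  sim <- embedded_panel(107, n_snps = 10L, n_cases = 50L, n_controls = 50L)
  ds <- sim$dataset
  idx <- c(2L, 5L)
  ct <- build_contingency(ds, idx)
  for (r in seq_along(ct$row_labels)) {
    g <- as.integer(strsplit(ct$row_labels[r], "/")[[1]])
    manual <- sum(ds$genotypes[, idx[1]] == g[1] & ds$genotypes[, idx[2]] == g[2])
    expect_identical(sum(ct$counts[r, ]), manual)
  }
})

test_that("statistics are invariant to sample order", {
  sim <- embedded_panel(108, n_snps = 8L, n_cases = 60L, n_controls = 60L)
  ds <- sim$dataset
  perm <- sample(n_samples <- nrow(ds$genotypes))
  ds2 <- genotype_dataset(ds$genotypes[perm, ], ds$phenotype[perm],
                          ds$snp_names)
  for (idx in list(c(1L, 2L), c(3L, 7L))) {
    expect_equal(k2_score(build_contingency(ds, idx)),
                 k2_score(build_contingency(ds2, idx)))
    expect_equal(lr_score(build_contingency(ds, idx)),
                 lr_score(build_contingency(ds2, idx)))
  }
})

test_that("batch scorer agrees with per-table scoring", {
  sim <- embedded_panel(109, n_snps = 12L, n_cases = 80L, n_controls = 80L)
  ds <- sim$dataset
  idx <- all_pairs(12L)[sample(66L, 15L), ]
  sc <- score_combinations(ds, idx)
  for (i in seq_len(nrow(idx))) {
    ct <- build_contingency(ds, idx[i, ])
    expect_equal(sc$k2[i], k2_score(ct), tolerance = 1e-10)
    expect_equal(sc$g[i], lr_score(ct), tolerance = 1e-10)
    expect_equal(sc$i_rows[i], nrow(ct$counts))
  }
  expect_equal(sc$lr, -sc$g)
  sc_raw <- score_combinations(ds, idx, lr_direction = "raw")
  expect_equal(sc_raw$lr, sc_raw$g)
})

test_that("HWE-based expectation is a valid alternative expectation model", {
  ds <- null_panel(110, n = 200L, n_snps = 6L)
  ct <- build_contingency(ds, c(1L, 2L))
  E <- expected_counts(ct, method = "hwe")
  expect_true(all(E >= 0))
  expect_equal(dim(E), dim(ct$counts))
  # with HWE-sampled background genotypes the two expectations are close
  expect_lt(max(abs(E - expected_counts(ct))) / ct$N, 0.05)
})
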