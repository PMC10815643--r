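test_that("position decoding floors, clips, repairs duplicates and sorts", {
  expect_identical(decode_position(c(3.7, 10.2), 20L), c(3L, 10L))
  expect_identical(decode_position(c(5.1, 5.9), 10L), c(5L, 6L))
  expect_identical(decode_position(c(10.9, 10.2), 10L), c(1L, 10L)) # cyclic
  expect_identical(decode_position(c(-3, 99), 10L), c(1L, 10L))
  set.seed(301)
  for (i in 1:50) {
    x <- runif(3, -5, 30)
    d <- decode_position(x, 25L)
    expect_identical(decode_position(d, 25L), d)  # idempotent
    expect_identical(d, sort(d))
    expect_identical(anyDuplicated(d), 0L)
  }
})

test_that("initial positions are uniform over the index box", {
  set.seed(302)
  P <- initialize_population(5000L, 2L, 100L)
  expect_true(all(P >= 1 & P < 101))
  se <- (100 / sqrt(12)) / sqrt(length(P))
  expect_lt(abs(mean(P) - 51), 3 * se)
  set.seed(7); a <- initialize_population(10L, 2L, 50L)
  set.seed(7); b <- initialize_population(10L, 2L, 50L)
  expect_identical(a, b)
  expect_error(initialize_population(10L, 5L, 3L), "n_snps")
})

test_that("spherical displacements preserve the scaled radius exactly", {
  set.seed(303)
  expect_identical(spherical_step(c(1, 2), c(1, 2), 0.7), c(0, 0))
  for (i in 1:50) {
    d <- sample(1:5, 1)
    a <- rnorm(d); b <- rnorm(d); f <- runif(1, 0.05, 1)
    s <- spherical_step(a, b, f)
    expect_equal(sqrt(sum(s^2)), f * sqrt(sum((a - b)^2)), tolerance = 1e-12)
  }
  s1 <- replicate(200, spherical_step(0, 3, 0.5))
  expect_setequal(unique(s1), c(-1.5, 1.5))
})

test_that("displacement directions are uniform on the circle", {
  set.seed(304)
  ang <- replicate(8000, {
    s <- spherical_step(c(0, 0), c(2, 0), 1)
    atan2(s[2], s[1])
  })
  counts <- table(cut(ang, seq(-pi, pi, length.out = 9)))
  p <- stats::chisq.test(as.integer(counts))$p.value
  expect_gt(p, 1e-4)
})

test_that("mutation is bounded by the two spherical radii", {
  set.seed(305)
  lo <- 1; hi <- 101
  for (i in 1:30) {
    xi <- runif(2, 40, 60); pb <- runif(2, 40, 60)
    r1 <- runif(2, 40, 60); r2 <- runif(2, 40, 60)
    f <- runif(1, 0.05, 0.3)
    t1 <- spherical_mutate(xi, pb, r1, r2, f, lo, hi)
    lim <- f * (sqrt(sum((xi - pb)^2)) + sqrt(sum((r1 - r2)^2)))
    expect_lte(sqrt(sum((t1 - xi)^2)), lim + 1e-9)
  }
  xi <- c(10, 20)
  expect_equal(spherical_mutate(xi, xi, xi, xi, 0.5, lo, hi), xi)
})

test_that("binomial crossover honours its rate and the forced coordinate", {
  set.seed(306)
  xi <- rep(0, 50); ti <- rep(1, 50)
  expect_identical(crossover(xi, ti, 1), ti)
  u0 <- crossover(xi, ti, 0)
  expect_identical(sum(u0), 1)   # only the forced coordinate
  freq <- mean(replicate(400, mean(crossover(xi, ti, 0.3))))
  expected <- 0.3 + 0.7 / 50
  expect_lt(abs(freq - expected), 0.02)
})

test_that("archive stays within capacity and inserts are retained last", {
  a <- matrix(numeric(0), 0, 2)
  set.seed(307)
  for (i in 1:5) a <- update_archive(a, c(i, i), capacity = 4L)
  expect_identical(nrow(a), 4L)
  expect_equal(a[4, ], c(5, 5))   # the newest member is never evicted
  b <- update_archive(matrix(numeric(0), 0, 2), c(1, 1), 10L)
  expect_identical(nrow(b), 1L)
})

test_that("scale factors come from truncated Cauchy draws around memory", {
  set.seed(308)
  mem <- history_memory(5L)
  expect_equal(mem$mF, rep(0.5, 5))
  f <- replicate(20000, sample_scale_factor(mem))
  expect_true(all(f > 0 & f <= 1))
  expect_lt(abs(stats::median(f) - 0.5), 0.02)
  hot <- structure(list(mF = 1.5, k_index = 1L, H = 1L),
                   class = "history_memory")
  fh <- replicate(2000, sample_scale_factor(hot))
  expect_gt(mean(fh == 1), 0.5)
})

test_that("success-history memory applies the weighted Lehmer mean", {
  mem <- history_memory(3L)
  mem <- update_memory(mem, 0.7, 1)
  expect_equal(mem$mF[1], 0.7)
  expect_identical(mem$k_index, 2L)
  mem2 <- update_memory(history_memory(3L), c(0.2, 0.8), c(1, 1))
  expect_equal(mem2$mF[1], 0.68)
  # empty success set copies the previous slot and cycles
  mem3 <- structure(list(mF = c(0.3, 0.5, 0.5), k_index = 2L, H = 3L),
                    class = "history_memory")
  mem3 <- update_memory(mem3, numeric(0))
  expect_equal(mem3$mF, c(0.3, 0.3, 0.5))
  expect_identical(mem3$k_index, 3L)
  set.seed(309)
  m <- history_memory(2L)
  for (i in 1:20) {
    m <- update_memory(m, runif(3, 0.01, 1), runif(3))
    expect_true(all(m$mF > 0 & m$mF <= 1))
  }
})

test_that("run_search is deterministic and respects a degenerate budget", {
  sim <- embedded_panel(310, n_snps = 20L, n_cases = 100L, n_controls = 100L)
  cfg <- run_config(seed = 99, population_size = 30L,
                    max_evaluations = 30L)
  a <- run_search(sim$dataset, cfg)
  b <- run_search(sim$dataset, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_identical(attr(a, "evaluations"), 30L)
  cfg2 <- cfg; cfg2$seed <- 100L
  expect_identical(attr(run_search(sim$dataset, cfg2), "evaluations"), 30L)
})

test_that("reported objectives re-evaluate to their stored values", {
  sim <- embedded_panel(311, n_snps = 25L, n_cases = 150L, n_controls = 150L)
  cfg <- run_config(seed = 5, population_size = 40L,
                    max_evaluations = 40L * 10L)
  res <- run_search(sim$dataset, cfg)
  idx <- do.call(rbind, attr(res, "indices"))
  sc <- score_combinations(sim$dataset, idx)
  expect_equal(res$K2, sc$k2, tolerance = 1e-12)
  expect_equal(res$G, sc$g, tolerance = 1e-12)
  # nondominated: no member dominates another
  for (i in seq_len(nrow(res))) {
    dom <- res$K2 <= res$K2[i] & res$LR <= res$LR[i] &
      (res$K2 < res$K2[i] | res$LR < res$LR[i])
    expect_false(any(dom))
  }
})

test_that("the search finds a strongly associated pair on a small panel", {
  sim <- embedded_panel(312, n_snps = 30L, n_cases = 400L, n_controls = 400L)
  cfg <- run_config(seed = 13, population_size = 60L,
                    max_evaluations = 60L * 25L)
  res <- run_search(sim$dataset, cfg)
  keys <- vapply(attr(res, "indices"), paste, character(1), collapse = "_")
  expect_true(paste(sim$truth$indices, collapse = "_") %in% keys)
  # exhaustive cross-check: the engine found the global K2 optimum
  sc <- score_combinations(sim$dataset, all_pairs(30L))
  expect_equal(min(res$K2), min(sc$k2), tolerance = 1e-10)
})
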