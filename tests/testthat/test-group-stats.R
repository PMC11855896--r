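test_that("the exact Mann-Whitney p matches full enumeration on small samples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2/20 rank assignments are as extreme
  expect_equal(res$method, "exact")

  withr::local_seed(71)
  for (i in 1:15) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- sample(1:1000, nx); y <- sample(setdiff(1:1000, x), ny)
    res <- mann_whitney_u(x, y)
    expect_equal(res$p, mw_enumeration_p(x, y), tolerance = 1e-12)
  }
})

test_that("identical or constant samples give p = 1", {
  x <- c(2, 4, 6, 8)
  expect_equal(suppressWarnings(mann_whitney_u(x, x)$p), 1)
  expect_warning(res <- mann_whitney_u(c(1, 1), c(1, 1, 1)), "constant")
  expect_equal(res$p, 1)
})

test_that("exact and normal-approximation p agree to 0.01 on tie-free samples", {
  withr::local_seed(73)
  for (i in 1:20) {
    nx <- sample(5:20, 1); ny <- sample(5:20, 1)
    if (nx * ny > 400) next
    x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
    pe <- mann_whitney_u(x, y, exact = TRUE)$p
    pa <- mann_whitney_u(x, y, exact = FALSE)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("swapping group labels preserves p and mirrors U", {
  withr::local_seed(79)
  x <- rnorm(12); y <- rnorm(15, 0.5)
  a <- mann_whitney_u(x, y)
  b <- mann_whitney_u(y, x)
  expect_equal(a$p, b$p)
  expect_equal(a$U, length(x) * length(y) - b$U)
})

test_that("Bonferroni thresholds reproduce the printed 4-dp values", {
  expect_equal(bonferroni_threshold(0.05, 6)$display, 0.0083)
  expect_equal(bonferroni_threshold(0.05, 13)$display, 0.0038)
  expect_equal(bonferroni_threshold(0.05, 20)$display, 0.0025)
  expect_equal(bonferroni_threshold(0.05, 1)$display, 0.05)
  expect_equal(bonferroni_threshold(0.05, 6)$threshold, 0.05 / 6)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("chi-squared follows the Pearson formula without Yates correction", {
  res <- chi_squared(matrix(c(10, 10, 10, 10), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  res <- chi_squared(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res$statistic, 40)   # hand computation: 4 cells of (10)^2/10
  expect_equal(res$df, 1)

  m <- matrix(c(12, 5, 7, 16, 3, 9), 2)
  expect_equal(suppressWarnings(chi_squared(m)$statistic),
               suppressWarnings(chi_squared(m[2:1, ])$statistic))
  expect_error(chi_squared(matrix(c(0, 0, 5, 7), 2)), "zero marginal")
  expect_warning(chi_squared(matrix(c(2, 30, 3, 40), 2)), "below 5")
})

test_that("group comparison reports per-family thresholds and decisions", {
  withr::local_seed(83)
  ids <- paste0("g", 1:40)
  feats <- data.frame(gene_id = ids,
                      f1 = c(rnorm(20, 0), rnorm(20, 3)),  # strong shift
                      f2 = rnorm(40),                      # null
                      f3 = rnorm(40), f4 = rnorm(40), f5 = rnorm(40),
                      f6 = rnorm(40))
  labels <- data.frame(gene_id = ids, class = rep(c("stable", "labile"), each = 20))
  res <- compare_groups(feats, labels, family = paste0("f", 1:6))
  expect_equal(nrow(res), 6)
  expect_equal(unique(res$alpha_corr), 0.0083)
  expect_true(res$significant[res$feature == "f1"])
  expect_false(res$significant[res$feature == "f2"])

  # two identical groups: everything p = 1
  feats2 <- data.frame(gene_id = ids, v = rep(c(1, 5, 9, 2), 10))
  same <- suppressWarnings(compare_groups(feats2, labels, family = "v"))
  expect_equal(same$p, 1)
  expect_false(same$significant)
})

test_that("label swap in compare_groups swaps medians but not p", {
  withr::local_seed(89)
  ids <- paste0("g", 1:30)
  feats <- data.frame(gene_id = ids, v = rnorm(30))
  lab1 <- data.frame(gene_id = ids, class = rep(c("stable", "labile"), 15))
  lab2 <- lab1
  lab2$class <- ifelse(lab1$class == "stable", "labile", "stable")
  r1 <- compare_groups(feats, lab1, family = "v")
  r2 <- compare_groups(feats, lab2, family = "v")
  expect_equal(r1$p, r2$p)
  expect_equal(r1$median_stable, r2$median_labile)
  expect_equal(r1$median_labile, r2$median_stable)
})
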