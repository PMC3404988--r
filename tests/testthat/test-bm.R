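test_that("the relative effect equals brute-force pair counting", {
  expect_equal(brunner_munzel(c(5, 5, 5), c(5, 5, 5))$p_hat, 0.5)
  expect_equal(brunner_munzel(c(5, 5, 5), c(5, 5, 5))$statistic, 0)
  expect_equal(brunner_munzel(c(1, 2, 3), c(4, 5, 6))$p_hat, 1.0)
  expect_equal(brunner_munzel(c(1, 3), c(2, 4))$p_hat, 0.75)
  set.seed(71)
  for (i in 1:50) {
    x <- sample(1:6, sample(2:8, 1), replace = TRUE)
    y <- sample(1:6, sample(2:8, 1), replace = TRUE)
    expect_equal(brunner_munzel(x, y)$p_hat, brute_p_hat(x, y))
  }
})

test_that("swapping the samples mirrors the relative effect", {
  set.seed(72)
  for (i in 1:25) {
    x <- rnorm(sample(2:9, 1))
    y <- rnorm(sample(2:9, 1))
    expect_equal(brunner_munzel(x, y)$p_hat, 1 - brunner_munzel(y, x)$p_hat)
  }
})

test_that("the compiled permutation statistic matches the R implementation", {
  set.seed(73)
  for (i in 1:25) {
    nx <- sample(2:7, 1); ny <- sample(2:7, 1)
    pooled <- sample(1:5, nx + ny, replace = TRUE)
    xidx <- utils::combn(nx + ny, nx)
    stats_cpp <- trflpr:::cpp_bm_assignments(pooled, xidx)
    k <- sample(ncol(xidx), 1)
    x <- pooled[xidx[, k]]
    y <- pooled[-xidx[, k]]
    expect_equal(stats_cpp[k], brunner_munzel(x, y)$statistic)
  }
})

test_that("small samples are enumerated exactly", {
  res <- permuted_bm_test(c(1, 2, 3), c(4, 5, 6))
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 20L)
  expect_equal(res$p_value, 0.1) # only the observed split and its mirror
  res_tie <- permuted_bm_test(c(2, 4, 7), c(2, 4, 7))
  expect_equal(res_tie$p_value, 1.0)
  expect_error(permuted_bm_test(c(1), c(2)), class = "trflpr_input_error")
})

test_that("Monte-Carlo and exhaustive p-values agree within sampling error", {
  set.seed(74)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5, 0.5)
    exact <- permuted_bm_test(x, y)
    mc <- permuted_bm_test(x, y, n_perm = 4000, seed = 100 + i,
                           exhaustive_limit = 10)
    expect_false(mc$exhaustive)
    se <- sqrt(exact$p_value * (1 - exact$p_value) / 4000)
    expect_lt(abs(mc$p_value - exact$p_value), 4 * se + 1e-3)
  }
})

test_that("Monte-Carlo p-values are seeded, reproducible and never zero", {
  x <- rnorm(12); y <- rnorm(12, 2)
  a <- permuted_bm_test(x, y, n_perm = 500, seed = 9)
  b <- permuted_bm_test(x, y, n_perm = 500, seed = 9)
  expect_identical(a$p_value, b$p_value)
  expect_gt(a$p_value, 0)
})

test_that("null permutation p-values are approximately uniform", {
  set.seed(75)
  pvals <- replicate(1000, {
    x <- rnorm(10); y <- rnorm(10)
    permuted_bm_test(x, y, n_perm = 499,
                     exhaustive_limit = 10)$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("tidy and glance return one-row summaries", {
  res <- permuted_bm_test(c(1, 2, 3), c(4, 5, 6))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_named(td, c("statistic", "p_hat", "p_value", "n_perm",
                     "exhaustive", "n_x", "n_y"))
  expect_equal(glance(res), td)
})

test_that("month comparisons extract per-sample abundances correctly", {
  profiles <- tibble::tibble(
    sample_id = rep(c("a", "b", "c", "d", "e", "f"), each = 1),
    month = rep(c("2005-06", "2005-08"), each = 3),
    category = "Casp",
    ra_pct = c(10, 12, 11, 60, 65, 62)
  )
  res <- compare_months(profiles, "Casp", "2005-06", "2005-08")
  expect_lt(res$p_value, 0.2)
  expect_equal(res$n_per_month, c(3L, 3L))
  expect_false(res$low_power)

  same <- tibble::tibble(sample_id = c("a", "b", "c", "d"),
                         month = rep(c("m1", "m2"), each = 2),
                         category = "X", ra_pct = c(10, 20, 10, 20))
  expect_equal(compare_months(same, "X", "m1", "m2")$p_value, 1.0)

  expect_error(compare_months(profiles, "Casp", "2005-06", "2099-01"),
               class = "trflpr_input_error")
  # both months lack the category, so the warning fires once per month
  expect_warning(
    expect_warning(compare_months(profiles, "Nope", "2005-06", "2005-08"),
                   "treated as zeros"),
    "treated as zeros"
  )
})

test_that("a simulated strong seasonal shift is detected with high power", {
  set.seed(76)
  hits <- 0L
  for (r in 1:200) {
    a <- pmin(pmax(rnorm(8, 10, 8), 0), 100)
    b <- pmin(pmax(rnorm(8, 60, 8), 0), 100)
    profiles <- tibble::tibble(
      sample_id = sprintf("s%02d", 1:16),
      month = rep(c("A", "B"), each = 8),
      category = "F",
      ra_pct = c(a, b)
    )
    res <- compare_months(profiles, "F", "A", "B")
    if (res$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.9)
})
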