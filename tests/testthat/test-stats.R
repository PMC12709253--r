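test_that("a dataset entirely above the reference forces the no-crossing arithmetic", {
  lengths <- seq(8, 23, length.out = 16)
  b <- tibble::tibble(length_um = seq(8, 23, length.out = 24),
                      lambda_um = pmin(seq(8, 23, length.out = 24), 15))
  a <- tibble::tibble(length_um = lengths,
                      lambda_um = pmin(lengths, 15) + 2)
  ct <- crossing_test(a, b)
  expect_equal(ct$N, 16)
  expect_equal(ct$n_crossings, 0)
  expect_equal(ct$t_stat, 8 / 2)
  expect_equal(ct$df, 8)
  expect_lt(ct$p_value, 0.01)
  expect_true(ct$significant)
})

test_that("strictly alternating residuals force the over-crossing arithmetic", {
  lengths <- seq(8, 23, length.out = 16)
  b <- tibble::tibble(length_um = c(7.9, 15, 23.1), lambda_um = c(0, 0, 0))
  a <- tibble::tibble(length_um = lengths,
                      lambda_um = rep(c(1, -1), 8))
  ct <- crossing_test(a, b)
  expect_equal(ct$n_crossings, 15)
  expect_equal(ct$t_stat, abs(15 - 8) / 2)
  expect_true(ct$significant)
})

test_that("exact-zero residuals inherit the previous sign and are flagged", {
  b <- tibble::tibble(length_um = c(8, 14, 20), lambda_um = c(8, 14, 20))
  a <- tibble::tibble(length_um = c(9, 10, 11, 12),
                      lambda_um = c(10, 10, 10, 10.5))  # third lies on the line
  ct <- crossing_test(a, b)
  expect_true("zero_residual" %in% ct$flags)
  # residual signs +, (0 -> +), -, -: one crossing
  expect_equal(ct$n_crossings, 1)
})

test_that("crossing test input contracts are enforced", {
  b <- tibble::tibble(length_um = c(8, 9, 10), lambda_um = c(8, 9, 10))
  expect_error(crossing_test(b[1:2, ], b), class = "ciliawave_input_error")
  far <- tibble::tibble(length_um = c(30, 31, 32), lambda_um = c(1, 2, 3))
  expect_error(crossing_test(far, b), class = "ciliawave_input_error")
})

test_that("same-curve noisy data give the same verdict in either direction", {
  curve <- function(L) pmin(L, 15)
  set.seed(21)
  for (i in 1:3) {
    la <- seq(8.2, 24.8, length.out = 20)
    lb <- seq(8, 25, length.out = 20)
    a <- tibble::tibble(length_um = la, lambda_um = curve(la) + rnorm(20))
    b <- tibble::tibble(length_um = lb, lambda_um = curve(lb) + rnorm(20))
    expect_false(crossing_test(a, b)$significant)
    expect_false(crossing_test(b, a)$significant)
  }
})

test_that("Bonferroni maps, clips, and never decreases p-values", {
  expect_equal(bonferroni(0.01, m = 5), 0.05)
  expect_equal(bonferroni(0.5, m = 3), 1)
  p <- c(0.001, 0.2, 0.9)
  expect_true(all(bonferroni(p, m = 4) >= p))
  expect_true(all(bonferroni(p, m = 4) <= 1))
  expect_error(bonferroni(c(0.1, 0.2), m = 1),
               class = "ciliawave_parameter_error")
  expect_error(bonferroni(1.2), class = "ciliawave_parameter_error")
})

test_that("Bonferroni controls the family-wise error under a uniform null", {
  set.seed(5)
  m <- 8
  fwe <- mean(replicate(2000, any(bonferroni(runif(m), m) < 0.05)))
  expect_lte(fwe, 0.05 + 3 * sqrt(0.05 * 0.95 / 2000))
})

test_that("an exact line is a significant slope with zero standard error", {
  res <- suppressWarnings(
    slope_significance(data.frame(x = 1:5, y = 2 * (1:5) + 1)))
  expect_equal(res$slope, 2, tolerance = 1e-12)
  expect_lt(res$slope_se, 1e-10)
  expect_true(res$significant)
})

test_that("the two-standard-error rule flags ~95% of null slopes as not significant", {
  set.seed(9)
  hits <- replicate(400, {
    x <- runif(30, 8, 25)
    slope_significance(x = x, y = rnorm(30))$significant
  })
  expect_equal(mean(!hits), 0.95, tolerance = 0.04 / 0.95)
})

test_that("the slope rule separates the proportional and saturated regimes", {
  set.seed(13)
  L_short <- runif(25, 8, 14.9)
  grow <- slope_significance(x = L_short,
                             y = L_short + rnorm(25, 0, 0.5))
  L_long <- runif(25, 15, 25)
  flat <- slope_significance(x = L_long,
                             y = 15 + rnorm(25, 0, 1.5))
  expect_true(grow$significant)
  expect_false(flat$significant)
})

test_that("regression input contracts are enforced", {
  expect_error(slope_significance(x = c(1, 1, 1), y = 1:3),
               class = "ciliawave_input_error")
  expect_error(slope_significance(x = 1:2, y = 1:2),
               class = "ciliawave_input_error")
})
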