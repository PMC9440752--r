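test_that("Kruskal-Wallis H matches the hand-computed rank-sum formula", {
  # 9 observations, no ties: rank sums 6, 15, 24
  # H = 12 / (9 * 10) * (36 + 225 + 576) / 3 - 3 * 10 = 7.2
  d <- tibble::tibble(
    v = c(1, 2, 3, 4, 5, 6, 7, 8, 9),
    g = rep(c("a", "b", "c"), each = 3)
  )
  kt <- kruskal_wallis(d, v, g)
  expect_equal(kt$statistic, 7.2)
  expect_equal(kt$df, 2)
  expect_equal(nrow(kt$pairwise), 3)
})

test_that("identical groups give H = 0 and p = 1", {
  d <- tibble::tibble(v = rep(5, 12), g = rep(c("a", "b", "c"), 4))
  kt <- suppressWarnings(kruskal_wallis(d, v, g))
  expect_equal(kt$statistic, 0)
  expect_equal(kt$p_value, 1)
})

test_that("the test is invariant under strictly monotone transforms", {
  set.seed(51)
  d <- tibble::tibble(
    v = rexp(40), g = rep(c("a", "b", "c", "d"), each = 10)
  )
  k1 <- kruskal_wallis(d, v, g)
  k2 <- kruskal_wallis(dplyr::mutate(d, v = exp(3 * v) + 1), v, g)
  expect_equal(k1$statistic, k2$statistic)
  expect_equal(k1$pairwise$p_raw, k2$pairwise$p_raw)
})

test_that("five treatments give four degrees of freedom and ten comparisons", {
  set.seed(52)
  d <- tibble::tibble(
    v = rpois(75, 4),
    g = rep(c("straight", "cleaned", "carried", "control", "simulated"), 15)
  )
  kt <- kruskal_wallis(d, v, g)
  expect_equal(kt$df, 4)
  expect_equal(nrow(kt$pairwise), 10)
  expect_true(all(kt$pairwise$p_holm >= kt$pairwise$p_raw))
  expect_error(kruskal_wallis(d[d$g == "straight", ], v, g), "two groups")
})

test_that("Holm adjustment follows the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  set.seed(53)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(holm_adjust(p) <= 1))
  # monotone in raw order
  o <- order(p)
  expect_true(all(diff(holm_adjust(p)[o]) >= 0))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("two-group linear model equals the closed-form pooled t test", {
  set.seed(54)
  d <- tibble::tibble(
    v = c(rnorm(200, 0, 1), rnorm(200, 0.4, 1)),
    g = rep(c("a", "b"), each = 200)
  )
  fit <- two_group_lm(d, v, g)
  x <- d$v[d$g == "a"]
  y <- d$v[d$g == "b"]
  sp <- sqrt(((199) * var(x) + (199) * var(y)) / 398)
  t_oracle <- (mean(y) - mean(x)) / (sp * sqrt(1 / 200 + 1 / 200))
  expect_equal(fit$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(fit$df, 398)

  # 16 + 15 observations leave 29 residual degrees of freedom
  d2 <- tibble::tibble(
    v = c(rnorm(16, 50, 8), rnorm(15, 48, 8)),
    g = rep(c("carried", "filmed"), c(16, 15))
  )
  expect_equal(two_group_lm(d2, v, g)$df, 29)

  same <- tibble::tibble(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(two_group_lm(same, v, g)$statistic, 0)
  expect_error(
    two_group_lm(tibble::tibble(v = rep(1, 6), g = rep(c("a", "b"), 3)), v, g),
    "zero variance"
  )
})
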