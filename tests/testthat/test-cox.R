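test_that("two identical groups give a zero log hazard ratio", {
  d <- tibble::tibble(
    duration = rep(c(100, 300, 700, 1500), 2),
    event = rep(c(TRUE, TRUE, FALSE, TRUE), 2),
    group = rep(c("a", "b"), each = 4)
  )
  fit <- cox_fit(d, duration, event, group)
  expect_equal(fit$coef, 0, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(tidy(fit)$hazard_ratio, 1, tolerance = 1e-10)
})

test_that("a four-observation fit matches direct enumeration of the partial likelihood", {
  d <- tibble::tibble(
    duration = c(2, 5, 7, 11),
    event = c(TRUE, TRUE, FALSE, TRUE),
    group = c("b", "a", "b", "a")
  )
  fit <- cox_fit(d, duration, event, group)
  # Breslow partial likelihood enumerated on a fine grid of beta
  x <- as.numeric(d$group == "b")
  pl <- function(b) {
    eta <- b * x
    risk <- exp(eta)
    sum(eta[d$event]) - sum(vapply(which(d$event), function(i) {
      log(sum(risk[d$duration >= d$duration[i]]))
    }, numeric(1)))
  }
  grid <- seq(-5, 5, by = 1e-4)
  b_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(unname(fit$coef), b_grid, tolerance = 1e-3)
})

test_that("estimates agree with the survival package on simulated data", {
  d <- generate_duration_cohort(n_per_group = 120, hazard_ratio = 2,
                                seed = 31)
  fit <- cox_fit(d, duration, event, group)
  ref <- survival::coxph(survival::Surv(duration, event) ~ group, data = d,
                         method = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-6)
  expect_equal(unname(fit$loglik["final"]), ref$loglik[2], tolerance = 1e-6)

  # rank-based partial likelihood: invariant to duration rescaling
  d2 <- dplyr::mutate(d, duration = duration * 3.7)
  expect_equal(cox_fit(d2, duration, event, group)$coef, fit$coef,
               tolerance = 1e-8)
})

test_that("parameter recovery holds over replicated cohorts", {
  # scaled-down version of the acceptance check: 30 replicates, n = 150/group
  set.seed(32)
  hr <- replicate(30, {
    d <- generate_duration_cohort(n_per_group = 150, hazard_ratio = 2)
    exp(cox_fit(d, duration, event, group)$coef)
  })
  expect_gt(mean(hr), 1.85)
  expect_lt(mean(hr), 2.15)
})

test_that("complete separation is flagged rather than silently returned", {
  d <- tibble::tibble(
    duration = c(1, 2, 3, 4, 100, 200, 300, 400),
    event = TRUE,
    group = rep(c("fast", "slow"), each = 4)
  )
  expect_warning(fit <- cox_fit(d, duration, event, group), "monotone")
  expect_true(fit$monotone)
})

test_that("frailty fit with theta forced to zero reproduces the plain fit", {
  d <- generate_duration_cohort(n_per_group = 60, hazard_ratio = 2,
                                frailty_sd = 0.5, n_clusters = 8, seed = 33)
  plain <- cox_fit(d, duration, event, group)
  forced <- frailty_fit(d, duration, event, group, cluster, theta = 0)
  expect_equal(forced$coef, plain$coef, tolerance = 1e-6)
  expect_equal(unname(forced$loglik["integrated"]),
               unname(plain$loglik["final"]))
  expect_equal(forced$theta_multiplier, 1)
})

test_that("frailty estimation recovers the simulated colony effect", {
  set.seed(34)
  est <- replicate(8, {
    d <- generate_duration_cohort(n_per_group = 150, hazard_ratio = 2,
                                  frailty_sd = 0.7, n_clusters = 10)
    frailty_fit(d, duration, event, group, cluster)$theta
  })
  expect_gt(mean(est), 0.4)
  expect_lt(mean(est), 1.0)
})

test_that("the frailty multiplier is the exponential of the frailty s.d.", {
  d <- generate_duration_cohort(n_per_group = 30, hazard_ratio = 2, seed = 35)
  f <- frailty_fit(d, duration, event, group, cluster, theta = 0.352)
  expect_equal(round(f$theta_multiplier, 3), 1.422)
  f2 <- frailty_fit(d, duration, event, group, cluster, theta = 0.020)
  expect_equal(round(f2$theta_multiplier, 3), 1.020)
})

test_that("likelihood-ratio comparison uses one degree of freedom", {
  d <- generate_duration_cohort(n_per_group = 60, hazard_ratio = 2, seed = 36)
  c0 <- cox_fit(d, duration, event, group)
  f0 <- frailty_fit(d, duration, event, group, cluster, theta = 0)
  out <- lrt_compare(c0, f0)
  expect_equal(out$statistic, 0)
  expect_equal(out$df, 1)
  expect_equal(out$p_value, 1)

  f1 <- frailty_fit(d, duration, event, group, cluster)
  out1 <- lrt_compare(c0, f1)
  expect_gte(out1$statistic, 0)
  expect_equal(out1$df, 1)

  d2 <- generate_duration_cohort(n_per_group = 50, hazard_ratio = 2, seed = 37)
  expect_error(
    lrt_compare(c0, cox_fit(d2, duration, event, group)), "nested"
  )
})

test_that("single-cluster frailty falls back to theta zero with a warning", {
  d <- generate_duration_cohort(n_per_group = 30, hazard_ratio = 2,
                                n_clusters = 1, seed = 38)
  expect_warning(f <- frailty_fit(d, duration, event, group, cluster),
                 "single cluster")
  expect_equal(f$theta, 0)
})
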