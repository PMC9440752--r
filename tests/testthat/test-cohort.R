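test_that("the default archetypes mirror the assay design", {
  arch <- treatment_archetypes()
  expect_equal(sum(arch$n_trials), 16 + 15 + 16 + 15 + 15 + 15 + 30)
  expect_setequal(
    unique(arch$treatment),
    c("straight", "sinusoidal", "cleaned", "carried", "control",
      "filmed", "simulated")
  )
  # carried and control move identically (exchangeable by construction)
  expect_equal(arch$homing_weight[arch$treatment == "carried"],
               arch$homing_weight[arch$treatment == "control"])
  expect_true(all(arch$homing_weight[arch$treatment == "simulated"] == 0))
})

test_that("cohorts are reproducible from the seed", {
  c1 <- generate_cohort(seed = 101, attach_crossings = FALSE)
  c2 <- generate_cohort(seed = 101, attach_crossings = FALSE)
  expect_identical(c1$outcomes, c2$outcomes)
  expect_identical(c1$colony_effects, c2$colony_effects)
  c3 <- generate_cohort(seed = 102, attach_crossings = FALSE)
  expect_false(identical(c1$outcomes, c3$outcomes))
})

test_that("cohort outcomes respect the censoring and emergence contracts", {
  coh <- generate_cohort(seed = 103, attach_crossings = FALSE)
  out <- coh$outcomes
  expect_true(all(out$duration[!out$event & !is.na(out$event)] == 1800))
  expect_true(all(is.na(out$duration[!out$emerged])))
  emerged <- out[out$emerged, ]
  expect_true(all(emerged$duration > 0))
  # quadrant occupancy sums to the tracked duration for returned ants in
  # the arms whose walk terminates at return (simulated walkers keep going)
  ret <- emerged[emerged$event & emerged$treatment != "simulated", ]
  expect_equal(ret$q1_s + ret$q2_s + ret$q3_s + ret$q4_s, ret$duration,
               tolerance = 1e-9)
  expect_error(
    generate_cohort(dplyr::mutate(treatment_archetypes(),
                                  emergence_prob = 2)),
    "emergence"
  )
})

test_that("robot-led arms return more often than carried arms by construction", {
  hits <- 0
  for (s in 1:10) {
    out <- generate_cohort(seed = 200 + s, attach_crossings = FALSE)$outcomes
    out <- out[out$emerged & out$treatment %in%
                 c("straight", "sinusoidal", "cleaned", "carried", "control"), ]
    robot <- out$treatment %in% c("straight", "sinusoidal", "cleaned")
    hits <- hits + (mean(out$event[robot]) > mean(out$event[!robot]))
  }
  expect_gte(hits, 9)
})

test_that("homing calibration is monotone and errors on unreachable targets", {
  a <- arena_spec("main")
  wp <- walker_params(max_steps = 900)
  set.seed(61)
  eps <- matrix(rnorm(400 * 900, 0, 5 * pi / 180), nrow = 400)
  h0 <- runif(400, 0, 2 * pi)
  p_at <- vapply(c(0, 0.005, 0.02, 0.1, 1), function(w) {
    params <- walker_params(homing_weight = w, goal = c(0, 0),
                            max_steps = 900)
    mean(robotandem:::walk_batch(400, params, a, stop_at_return = TRUE,
                                 turn_angles = eps, headings = h0)$returned)
  }, numeric(1))
  expect_true(all(diff(p_at) >= 0))

  # the pure CRW baseline already returns far more often than 2%
  expect_error(calibrate_homing(0.02, n_sim = 300, seed = 62),
               "achievable")

  w <- calibrate_homing(0.8, n_sim = 800, tol = 0.03, seed = 63)
  params <- walker_params(homing_weight = as.numeric(w), goal = c(0, 0))
  set.seed(64)
  fresh <- mean(robotandem:::walk_batch(
    800, params, a, stop_at_return = TRUE
  )$returned)
  expect_lt(abs(fresh - 0.8), 0.05)
})

test_that("the report bundle is complete and reproducible", {
  dir1 <- withr::local_tempdir()
  rep1 <- reproduce_report(seed = 71, dir = dir1)
  expect_true(all(file.exists(file.path(dir1, c(
    "outcomes.tsv", "km_pooled.csv", "proportions.tsv", "holm_matrix.tsv",
    "fisher.json", "manifest.json", "km_pooled.png", "hazard_pooled.png",
    "crossings.png"
  )))))
  expect_equal(rep1$lrt$df, 1)
  expect_true(rep1$fisher$estimate > 0)

  dir2 <- withr::local_tempdir()
  rep2 <- reproduce_report(seed = 71, dir = dir2)
  expect_identical(rep1$manifest$config_hash, rep2$manifest$config_hash)
  expect_identical(rep1$proportions, rep2$proportions)
  # robot-led homing advantage propagates to the pooled hazard ratio
  expect_gt(tidy(rep1$cox)$hazard_ratio, 1)
})
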