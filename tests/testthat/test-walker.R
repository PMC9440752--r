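test_that("parameter validation enforces the movement-model contract", {
  expect_error(walker_params(step_mm = 0), "step_mm")
  expect_error(walker_params(turn_sd_deg = -1), "turn_sd_deg")
  expect_error(walker_params(homing_weight = 1.5), "homing_weight")
  expect_error(walker_params(homing_weight = 0.5), "goal")
  expect_error(
    simulate_walker(walker_params(), arena_spec("main"), start = c(5000, 0)),
    "outside"
  )
})

test_that("zero-noise limits are exact", {
  a <- arena_spec("main")
  # sigma = 0, w = 0: straight ray along the initial heading
  p <- simulate_walker(walker_params(turn_sd_deg = 0, max_steps = 100), a,
                       start = c(360, 0), initial_heading = pi / 2)
  expect_equal(p$x_mm, rep(360, 101))
  expect_equal(p$y_mm, seq(0, 200, by = 2))
  expect_equal(path_length(p), 100 * 2)

  # w = 1, sigma = 0: deterministic homing reaches the goal in D / step steps
  p <- simulate_walker(
    walker_params(turn_sd_deg = 0, homing_weight = 1, goal = c(0, 0),
                  max_steps = 200), a,
    start = c(300, 0), initial_heading = pi / 2
  )
  expect_equal(unlist(p[151, c("x_mm", "y_mm")]), c(x_mm = 0, y_mm = 0),
               tolerance = 1e-9)
})

test_that("fixed step length makes path length exactly steps * step", {
  # started mid-arena with a reach shorter than any wall distance, so the
  # polyline is unfolded and its length is exactly steps * step
  set.seed(3)
  p <- simulate_walker(walker_params(max_steps = 200), arena_spec("main"),
                       start = c(400, 0))
  expect_equal(path_length(p), 200 * 2, tolerance = 1e-9)
  expect_equal(p$t_s, 0:200) # 1 step/s time base
})

test_that("reflecting boundaries keep every sample inside the arena", {
  a <- arena_spec(width_mm = 600, height_mm = 200, origin_offset_mm = 100)
  set.seed(4)
  for (i in 1:5) {
    p <- simulate_walker(walker_params(turn_sd_deg = 30, max_steps = 2000), a,
                         start = c(0, 0))
    expect_true(all(p$x_mm >= a$xlim[1] & p$x_mm <= a$xlim[2]))
    expect_true(all(p$y_mm >= a$ylim[1] & p$y_mm <= a$ylim[2]))
  }
})

test_that("heading autocorrelation decays as c^k for the pure CRW", {
  set.seed(5)
  a <- arena_spec("main")
  n_rep <- 400
  n_steps <- 60
  cosk <- matrix(NA_real_, n_rep, 5)
  for (r in seq_len(n_rep)) {
    p <- simulate_walker(walker_params(max_steps = n_steps), a,
                         start = c(400, 0))
    ang <- atan2(diff(p$y_mm), diff(p$x_mm))
    for (k in 1:5) {
      cosk[r, k] <- mean(cos(ang[(1 + k):n_steps] - ang[1:(n_steps - k)]))
    }
  }
  c1 <- exp(-(5 * pi / 180)^2 / 2)
  for (k in 1:5) {
    est <- mean(cosk[, k])
    se <- sd(cosk[, k]) / sqrt(n_rep)
    expect_lt(abs(est - c1^k), 3 * se + 1e-4)
  }
})

test_that("mean squared displacement follows the CRW closed form", {
  # scaled-down version of the full Monte-Carlo check in the acceptance
  # suite: 2000 walkers of 200 steps
  set.seed(6)
  a <- arena_spec("main")
  params <- walker_params(max_steps = 200)
  eps <- matrix(rnorm(2000 * 200, 0, 5 * pi / 180), nrow = 2000)
  h0 <- runif(2000, 0, 2 * pi)
  res <- robotandem:::walk_batch(2000, params, a, start = c(360, 0),
                                 turn_angles = eps, headings = h0)
  theory <- crw_msd_theory(200, 2, 5 * pi / 180)
  expect_lt(abs(mean(res$net_r2) - theory),
            3 * sd(res$net_r2) / sqrt(2000))
})

test_that("the simulated treatment is reproducible and bounded", {
  r1 <- run_simulated_treatment("straight", n = 6, seed = 9,
                                params = walker_params(max_steps = 300))
  r2 <- run_simulated_treatment("straight", n = 6, seed = 9,
                                params = walker_params(max_steps = 300))
  expect_identical(r1, r2)
  expect_equal(nrow(r1), 6)
  expect_true(all(r1$path_length_mm <= 300 * 2 + 1e-9))
  expect_true(all(r1$crossings >= 0))
  expect_error(run_simulated_treatment("straight", n = 0), "positive")
})

test_that("noise-free walkers parallel to the leader path never cross it", {
  leader <- leader_path(leader_path_spec(preset = "straight"))
  a <- arena_spec("main")
  for (offset in c(-40, 20, 60)) {
    p <- simulate_walker(
      walker_params(turn_sd_deg = 0, max_steps = 200), a,
      start = c(360, offset), initial_heading = pi
    )
    expect_equal(count_crossings(p, leader), 0)
  }
})
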