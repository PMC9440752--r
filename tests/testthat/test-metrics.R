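test_that("crossing counts handle canonical configurations", {
  refl <- tibble::tibble(x_mm = c(-2, 12), y_mm = c(0, 0))
  # one proper crossing
  expect_equal(count_crossings(
    tibble::tibble(x_mm = c(0, 10), y_mm = c(-1, 1)), refl
  ), 1)
  # disjoint parallels
  expect_equal(count_crossings(
    tibble::tibble(x_mm = c(0, 10), y_mm = c(1, 1)), refl
  ), 0)
  # pass-through exactly at a vertex counts once
  expect_equal(count_crossings(
    tibble::tibble(x_mm = c(0, 5, 10), y_mm = c(-1, 0, 1)), refl
  ), 1)
  # tangential touch at a vertex counts nothing
  expect_equal(count_crossings(
    tibble::tibble(x_mm = c(0, 5, 10), y_mm = c(-1, 0, -1)), refl
  ), 0)
  # collinear overlap: one crossing per transversal entry
  expect_equal(count_crossings(
    tibble::tibble(x_mm = c(0, 2, 4, 6, 8), y_mm = c(-1, 0, 0, 0, 1)), refl
  ), 1)
  expect_equal(count_crossings(
    tibble::tibble(x_mm = c(0, 2, 4, 6, 8), y_mm = c(-1, 0, 0, 0, -1)), refl
  ), 0)
  expect_error(count_crossings(
    tibble::tibble(x_mm = 1, y_mm = 1), refl
  ), "2 samples")
})

test_that("a straight return along the midline crosses the sinusoid like the sign-change oracle", {
  leader <- leader_path(leader_path_spec(preset = "sinusoidal"))
  ret <- tibble::tibble(x_mm = seq(360, 0, by = -1), y_mm = 0)
  oracle <- sign_change_crossings(leader, 360, 0, -1, 0)
  expect_equal(count_crossings(ret, leader), oracle)
  expect_equal(count_crossings(leader, ret), oracle) # symmetry holds here too
})

test_that("crossing counts match the brute-force oracle on seeded walkers", {
  leader <- leader_path(leader_path_spec(preset = "sinusoidal"))
  set.seed(11)
  a <- arena_spec("main")
  for (r in 1:15) {
    traj <- simulate_walker(walker_params(max_steps = 400), a,
                            start = c(250, 0))
    expect_identical(count_crossings(traj, leader),
                     brute_crossings(traj, leader))
  }
})

test_that("crossing counts are symmetric and rigid-motion invariant", {
  set.seed(12)
  a <- arena_spec("main")
  leader <- leader_path(leader_path_spec(preset = "sinusoidal"))
  for (r in 1:5) {
    traj <- simulate_walker(walker_params(max_steps = 300), a,
                            start = c(200, 0))
    n0 <- count_crossings(traj, leader)
    expect_identical(count_crossings(leader, traj), n0)
    th <- runif(1, 0, 2 * pi)
    shift <- runif(2, -100, 100)
    rot <- function(p) tibble::tibble(
      x_mm = cos(th) * p$x_mm - sin(th) * p$y_mm + shift[1],
      y_mm = sin(th) * p$x_mm + cos(th) * p$y_mm + shift[2]
    )
    expect_identical(count_crossings(rot(traj), rot(leader)), n0)
  }
})

test_that("path length sums consecutive sample distances", {
  expect_equal(path_length(tibble::tibble(x_mm = c(0, 3, 3),
                                          y_mm = c(0, 0, 4))), 7)
  expect_equal(path_length(tibble::tibble(x_mm = 1, y_mm = 1)), 0)
})

test_that("quadrant occupancy attributes intervals by midpoint and conserves time", {
  a <- arena_spec("main")
  # stationary in quadrant 2 for 100 s
  still <- tibble::tibble(t_s = seq(0, 100, by = 10), x_mm = 500, y_mm = 50)
  qt <- quadrant_times(still, a)
  expect_equal(qt$time_s, c(0, 100, 0, 0))

  set.seed(13)
  traj <- simulate_walker(walker_params(max_steps = 500), a)
  qt <- quadrant_times(traj, a)
  expect_equal(sum(qt$time_s), max(traj$t_s) - min(traj$t_s))

  # a square loop centred on the placement mark spends a quarter in each
  # quadrant, up to one sample interval
  tt <- seq(0, 80, by = 0.1)
  side <- 20
  sq <- tibble::tibble(
    t_s = tt,
    x_mm = 360 + side * c(seq(-1, 1, length.out = 201)[-201],
                          rep(1, 200),
                          seq(1, -1, length.out = 201)[-201],
                          rep(-1, 201))[seq_along(tt)],
    y_mm = side * c(rep(1, 200),
                    seq(1, -1, length.out = 201)[-201],
                    rep(-1, 200),
                    seq(-1, 1, length.out = 202))[seq_along(tt)]
  )
  qt <- quadrant_times(sq, a)
  expect_true(all(abs(qt$time_s - 20) <= 0.2 + 1e-9))
  expect_error(quadrant_times(sq[0, ], a), "empty")
})

test_that("outcome extraction applies the censoring rule", {
  a <- arena_spec("main")
  entering <- tibble::tibble(
    t_s = c(0, 450, 900, 1000), x_mm = c(360, 250, 100, 50), y_mm = 0
  )
  out <- extract_outcome(entering, a, "carried", colony = 3)
  expect_true(out$event)
  expect_equal(out$duration, 900) # first sample inside the return region
  expect_equal(out$treatment, "carried")

  never <- tibble::tibble(t_s = seq(0, 1800, by = 60), x_mm = 500, y_mm = 100)
  out <- extract_outcome(never, a, "straight", colony = 1)
  expect_false(out$event)
  expect_equal(out$duration, 1800) # censored at the trial limit

  inside <- tibble::tibble(t_s = 0:2, x_mm = c(0, 5, 10), y_mm = 0)
  expect_error(extract_outcome(inside, a, "carried", 1), "inside")
})

test_that("outcomes attach crossing counts when a leader path is supplied", {
  a <- arena_spec("main")
  leader <- leader_path(leader_path_spec(preset = "straight"))
  traj <- tibble::tibble(
    t_s = 0:3, x_mm = c(360, 200, 200, 100), y_mm = c(10, 10, -10, -10)
  )
  out <- extract_outcome(traj, a, "sinusoidal", 2, leader = leader)
  expect_equal(out$crossings, 1L)
  out2 <- extract_outcome(traj, a, "sinusoidal", 2)
  expect_true(is.na(out2$crossings))
})
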