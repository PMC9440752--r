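#' Correlated-random-walk parameters
#'
#' Movement model for the simulated walker: at each step the heading turns
#' by a Gaussian angle (mean 0, s.d. `turn_sd_deg`), optionally blended
#' towards a goal, and the walker advances `step_mm` along the new heading.
#' Defaults follow the simulated-treatment walker: 2 mm steps (about one
#' worker body length) and a 5 degree turning s.d.  With
#' `homing_weight = 0` this is the pure correlated random walk; a positive
#' weight `w` pulls each heading a fraction `w` of the way towards the
#' bearing of `goal` (wrapped difference), a minimal homing extension used
#' by the synthetic cohorts.
#'
#' The walker has no intrinsic time base; `step_rate` converts steps to
#' seconds (default 1 step/s, i.e. 2 mm/s, the leader's programmed speed),
#' so the 30 min censor limit corresponds to 1800 steps.
#'
#' @param step_mm Step length (mm), > 0.
#' @param turn_sd_deg Turning-angle s.d. (degrees), >= 0.
#' @param step_rate Steps per second, > 0.
#' @param homing_weight Goal-bias weight in `[0, 1]`; 0 = pure CRW.
#' @param goal Optional goal point `c(x, y)`; required when
#'   `homing_weight > 0`.
#' @param boundary Wall policy: `"reflect"` (specular), `"clip"` or
#'   `"absorb"`.
#' @param max_steps Maximum number of steps, >= 1.
#' @returns A `walker_params` list.
#' @examples
#' walker_params()
#' @export
walker_params <- function(step_mm = 2, turn_sd_deg = 5, step_rate = 1,
                          homing_weight = 0, goal = NULL,
                          boundary = c("reflect", "clip", "absorb"),
                          max_steps = 1800) {
  boundary <- arg_match(boundary)
  if (step_mm <= 0) abort("`step_mm` must be > 0")
  if (turn_sd_deg < 0) abort("`turn_sd_deg` must be >= 0")
  if (step_rate <= 0) abort("`step_rate` must be > 0")
  if (homing_weight < 0 || homing_weight > 1) {
    abort("`homing_weight` must be in [0, 1]")
  }
  if (homing_weight > 0 && is.null(goal)) {
    abort("`homing_weight` > 0 requires a `goal`")
  }
  if (max_steps < 1 || max_steps != round(max_steps)) {
    abort("`max_steps` must be a positive integer")
  }
  structure(list(
    step_mm = step_mm, turn_sd_deg = turn_sd_deg, step_rate = step_rate,
    homing_weight = homing_weight, goal = goal, boundary = boundary,
    max_steps = as.integer(max_steps)
  ), class = "walker_params")
}

boundary_code <- function(boundary) {
  match(boundary, c("reflect", "clip", "absorb")) - 1L
}

#' Simulate one correlated random walker
#'
#' Runs the walker of [walker_params()] inside an arena.  Heading update
#' per step: `theta <- theta + eps + w * wrap(bearing_to_goal - theta)`
#' with `eps ~ N(0, turn_sd)`; the position advances `step_mm` along the
#' new heading; the boundary policy is applied at the walls.  Timestamps
#' are `k / step_rate`.  The walk terminates at `max_steps`, on absorption,
#' or (when `stop_at_return = TRUE`) on first entering the return region.
#' Turning angles and the initial heading are drawn from R's RNG, so
#' results are reproducible under `set.seed()`.
#'
#' @param params A [walker_params()].
#' @param arena An [arena_spec()].
#' @param start Start point, default the placement mark.
#' @param initial_heading Initial heading (radians); default drawn
#'   uniformly on `[0, 2*pi)`.
#' @param stop_at_return Terminate on entering the return region?
#' @returns A tibble `t_s`, `x_mm`, `y_mm` with attributes `returned`,
#'   `absorbed`, `steps` and `source = "walker"`.
#' @examples
#' set.seed(1)
#' path <- simulate_walker(walker_params(), arena_spec("main"))
#' nrow(path)
#' @export
simulate_walker <- function(params, arena, start = arena$placement_mark,
                            initial_heading = NULL,
                            stop_at_return = FALSE) {
  stopifnot(inherits(params, "walker_params"), inherits(arena, "arena_spec"))
  if (start[1] < arena$xlim[1] || start[1] > arena$xlim[2] ||
      start[2] < arena$ylim[1] || start[2] > arena$ylim[2]) {
    abort("`start` lies outside the arena")
  }
  heading0 <- initial_heading %||% runif(1, 0, 2 * pi)
  eps <- rnorm(params$max_steps, 0, params$turn_sd_deg * pi / 180)
  goal <- params$goal %||% c(0, 0)
  res <- walk_path_cpp(
    eps, heading0, start[1], start[2], params$step_mm,
    params$homing_weight, goal[1], goal[2], !is.null(params$goal),
    params$step_rate,
    arena$xlim[1], arena$xlim[2], arena$ylim[1], arena$ylim[2],
    boundary_code(params$boundary), stop_at_return,
    arena$dish_side_mm / 2, arena$return_radius_mm
  )
  out <- tibble(t_s = res$t, x_mm = res$x, y_mm = res$y)
  attr(out, "source") <- "walker"
  attr(out, "returned") <- res$returned
  attr(out, "absorbed") <- res$absorbed
  attr(out, "steps") <- res$steps
  out
}

# Batch summary simulation (no stored paths); turning angles and headings
# are drawn here so R's RNG governs everything.
walk_batch <- function(n, params, arena, start = arena$placement_mark,
                       stop_at_return = FALSE, turn_angles = NULL,
                       headings = NULL) {
  eps <- turn_angles %||% matrix(
    rnorm(n * params$max_steps, 0, params$turn_sd_deg * pi / 180),
    nrow = n
  )
  heading0 <- headings %||% runif(n, 0, 2 * pi)
  goal <- params$goal %||% c(0, 0)
  res <- walk_batch_cpp(
    eps, heading0, start[1], start[2], params$step_mm,
    params$homing_weight, goal[1], goal[2], !is.null(params$goal),
    params$step_rate,
    arena$xlim[1], arena$xlim[2], arena$ylim[1], arena$ylim[2],
    boundary_code(params$boundary), stop_at_return,
    arena$dish_side_mm / 2, arena$return_radius_mm
  )
  as_tibble(as.data.frame(res))
}

#' Run the simulated treatment
#'
#' Simulates `n` independent correlated random walkers released at the
#' placement mark with uniform initial headings (2 mm steps, 5 degree
#' turning s.d., no homing bias) and records, per replicate, the number of
#' crossings of the programmed leader path and the walker's path length.
#' The walkers run for the full `max_steps` (default 1800, the censor
#' limit at 1 step/s); recording length and crossings, not returns,
#' mirrors the assay's simulated treatment.
#'
#' @param path_type `"straight"` or `"sinusoidal"`: which leader preset the
#'   crossings are counted against.
#' @param n Number of replicate walkers (the assay used 15 per path type).
#' @param seed Optional integer seed.
#' @param params,arena Walker parameters and arena (defaults as above).
#' @returns A tibble `replicate`, `crossings`, `path_length_mm`.
#' @examples
#' run_simulated_treatment("straight", n = 3, seed = 1)
#' @export
run_simulated_treatment <- function(path_type = c("straight", "sinusoidal"),
                                    n = 15, seed = NULL,
                                    params = walker_params(),
                                    arena = arena_spec("main")) {
  path_type <- arg_match(path_type)
  if (n <= 0) abort("`n` must be positive")
  if (!is.null(seed)) set.seed(seed)
  leader <- leader_path(leader_path_spec(preset = path_type))
  purrr::map_dfr(seq_len(n), function(i) {
    traj <- simulate_walker(params, arena, stop_at_return = FALSE)
    tibble(
      replicate = i,
      crossings = count_crossings(traj, leader),
      path_length_mm = path_length(traj)
    )
  })
}
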