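# Synthetic cohorts emulating the assay's treatment structure, so every
# pipeline stage can run without any recorded tracking data.

#' Default treatment archetypes
#'
#' One row per simulated treatment arm, mirroring the assay design:
#' robot-led arms (straight n = 16, sinusoidal n = 15, cleaned n = 16),
#' carried (n = 15), control (n = 15, the leader replayed at its mean
#' observed speeds before a carried release), filmed (n = 15, smaller
#' arena), and the simulated correlated random walkers (15 against each
#' leader path).  Robot-led ants move with a homing bias
#' (`homing_weight = homing_robot`, calibrated with [calibrate_homing()]
#' so that about 77% return within the censor limit, the return
#' probability implied by the assay's pooled odds ratio at the carried
#' baseline); carried-type ants are pure correlated random walkers
#' (`homing_carried = 0`, about 52% return); simulated walkers have no
#' bias and no return rule.
#' `leader_ref` names the leader preset against which path crossings are
#' counted.
#'
#' @param homing_robot,homing_carried Homing weights of the robot-led and
#'   carried archetypes (defaults calibrated with [calibrate_homing()]).
#' @param emergence_prob Probability that an ant emerges from the new nest
#'   within the emergence limit; non-emerging trials are aborted.
#' @returns A tibble with columns `treatment`, `n_trials`, `homing_weight`,
#'   `leader_ref`, `arena`, `emergence_prob`, `stop_at_return`.
#' @examples
#' treatment_archetypes()
#' @export
treatment_archetypes <- function(homing_robot = 0.0019036,
                                 homing_carried = 0,
                                 emergence_prob = 0.9) {
  tibble(
    treatment = c(
      "straight", "sinusoidal", "cleaned", "carried", "control",
      "filmed", "simulated", "simulated"
    ),
    n_trials = c(16L, 15L, 16L, 15L, 15L, 15L, 15L, 15L),
    homing_weight = c(
      homing_robot, homing_robot, homing_robot,
      homing_carried, homing_carried, homing_carried, 0, 0
    ),
    leader_ref = c(
      "straight", "sinusoidal", "straight", "straight",
      "control_straight", NA, "straight", "sinusoidal"
    ),
    arena = c(rep("main", 5), "filmed", "main", "main"),
    emergence_prob = c(rep(emergence_prob, 6), 1, 1),
    stop_at_return = c(rep(TRUE, 6), FALSE, FALSE)
  )
}

#' Generate a synthetic assay cohort
#'
#' Simulates one full cohort under the archetype table: each trial draws a
#' colony from a pool of `n_colonies`, applies the colony's log-normal
#' frailty multiplier `exp(frailty_sd * Z_colony)` to its archetype's
#' homing weight (capped at 1), simulates the walker from the placement
#' mark, and extracts the censored [extract_outcome()] row.  Non-emerging
#' trials (probability `1 - emergence_prob`) are aborted before the walk
#' and carry `NA` durations.  Everything is drawn from R's RNG under
#' `set.seed(seed)`, so a cohort is reproducible from `(archetypes, seed)`.
#'
#' @param archetypes An archetype tibble, see [treatment_archetypes()].
#' @param seed Integer seed.
#' @param n_colonies Size of the colony pool.
#' @param frailty_sd True colony frailty s.d. on the log homing-weight
#'   scale.
#' @param attach_crossings Count crossings against each arm's reference
#'   leader path?  (Skipping them speeds up large simulation studies.)
#' @param keep_trajectories Keep the simulated paths (as a list column of
#'   tibbles)?
#' @param walker Base movement parameters; the archetype's homing weight
#'   and termination rule override fields per trial.
#' @returns A `cohort_result` list: `outcomes` (one row per trial),
#'   `trajectories` (list or `NULL`), `colony_effects`, `archetypes`,
#'   `seed`.
#' @examples
#' coh <- generate_cohort(seed = 1, attach_crossings = FALSE)
#' dplyr::count(coh$outcomes, treatment, event)
#' @export
generate_cohort <- function(archetypes = treatment_archetypes(), seed = 1,
                            n_colonies = 10, frailty_sd = 0.35,
                            attach_crossings = TRUE,
                            keep_trajectories = FALSE,
                            walker = walker_params()) {
  stopifnot(is.data.frame(archetypes), all(archetypes$n_trials > 0))
  if (any(archetypes$emergence_prob < 0 | archetypes$emergence_prob > 1)) {
    abort("emergence probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  z <- rnorm(n_colonies)
  arenas <- list(
    main = arena_spec("main"),
    filmed = arena_spec("filmed")
  )
  leaders <- new.env(parent = emptyenv())
  get_leader <- function(preset) {
    if (is.na(preset)) return(NULL)
    if (is.null(leaders[[preset]])) {
      leaders[[preset]] <- leader_path(leader_path_spec(preset = preset))
    }
    leaders[[preset]]
  }

  rows <- list()
  trajs <- list()
  trial <- 0
  for (i in seq_len(nrow(archetypes))) {
    arch <- archetypes[i, ]
    arena <- arenas[[arch$arena]]
    leader <- if (attach_crossings) get_leader(arch$leader_ref) else NULL
    for (k in seq_len(arch$n_trials)) {
      trial <- trial + 1
      id <- sprintf("%s_%02d", arch$treatment, k)
      colony <- sample.int(n_colonies, 1)
      emerged <- runif(1) < arch$emergence_prob
      if (!emerged) {
        rows[[trial]] <- tibble(
          trial_id = id, treatment = arch$treatment, colony = colony,
          duration = NA_real_, event = NA, crossings = NA_integer_,
          path_length = NA_real_, q1_s = NA_real_, q2_s = NA_real_,
          q3_s = NA_real_, q4_s = NA_real_, emerged = FALSE
        )
        next
      }
      w <- min(1, arch$homing_weight * exp(frailty_sd * z[colony]))
      params <- walker_params(
        step_mm = walker$step_mm, turn_sd_deg = walker$turn_sd_deg,
        step_rate = walker$step_rate, homing_weight = w,
        goal = if (w > 0) c(0, 0) else NULL,
        boundary = walker$boundary, max_steps = walker$max_steps
      )
      traj <- simulate_walker(params, arena,
        stop_at_return = arch$stop_at_return
      )
      rows[[trial]] <- extract_outcome(
        traj, arena, arch$treatment, colony,
        leader = leader, trial_id = id
      )
      if (keep_trajectories) trajs[[id]] <- traj
    }
  }
  structure(list(
    outcomes = bind_rows(rows),
    trajectories = if (keep_trajectories) trajs else NULL,
    colony_effects = tibble(colony = seq_len(n_colonies), z = z),
    archetypes = archetypes,
    frailty_sd = frailty_sd,
    seed = seed
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> seed %d: %d trials, %d treatments, %d colonies\n",
    x$seed, nrow(x$outcomes), length(unique(x$outcomes$treatment)),
    nrow(x$colony_effects)
  ))
  invisible(x)
}

#' Calibrate the homing weight against a target return probability
#'
#' Monte-Carlo bisection: simulates `n_sim` walkers (common random numbers
#' across candidate weights, so the estimated return probability is
#' monotone in `w`) and bisects `w` on `[0, 1]` until the estimated
#' probability of returning before the censor limit is within `tol` of
#' `target`.  If the target lies outside the achievable range at the given
#' movement parameters, an error reports that range.
#'
#' @param target Desired return probability, in (0, 1).
#' @param walker Base [walker_params()] (its `homing_weight` is ignored).
#' @param arena An [arena_spec()].
#' @param n_sim Walkers per Monte-Carlo evaluation.
#' @param tol Acceptable absolute error on the return probability.
#' @param seed Seed for the common random numbers.
#' @returns The calibrated weight `w`, with the achieved probability as
#'   attribute `achieved`.
#' @examples
#' \donttest{
#' calibrate_homing(0.6, n_sim = 500)
#' }
#' @export
calibrate_homing <- function(target, walker = walker_params(),
                             arena = arena_spec("main"), n_sim = 2000,
                             tol = 0.02, seed = 1) {
  if (target <= 0 || target >= 1) abort("`target` must be in (0, 1)")
  set.seed(seed)
  eps <- matrix(
    rnorm(n_sim * walker$max_steps, 0, walker$turn_sd_deg * pi / 180),
    nrow = n_sim
  )
  headings <- runif(n_sim, 0, 2 * pi)
  p_hat <- function(w) {
    params <- walker_params(
      step_mm = walker$step_mm, turn_sd_deg = walker$turn_sd_deg,
      step_rate = walker$step_rate, homing_weight = w, goal = c(0, 0),
      boundary = walker$boundary, max_steps = walker$max_steps
    )
    mean(walk_batch(n_sim, params, arena,
      stop_at_return = TRUE,
      turn_angles = eps, headings = headings
    )$returned)
  }
  p0 <- p_hat(0)
  p1 <- p_hat(1)
  if (target < p0 - tol || target > p1 + tol) {
    abort(sprintf(
      "target %.3f unreachable: achievable return probability is [%.3f, %.3f]",
      target, p0, p1
    ))
  }
  lo <- 0
  hi <- 1
  for (it in 1:25) {
    mid <- (lo + hi) / 2
    if (p_hat(mid) < target) lo <- mid else hi <- mid
  }
  w <- (lo + hi) / 2
  achieved <- p_hat(w)
  if (abs(achieved - target) >= tol) {
    abort(sprintf(
      "calibration did not reach target %.3f (achieved %.3f)",
      target, achieved
    ))
  }
  structure(w, achieved = achieved)
}

#' Duration-level synthetic cohort
#'
#' A generator working directly on event times (no trajectories):
#' exponential return durations with a group hazard ratio and an exactly
#' log-normal cluster frailty, right-censored at `censor_limit`.  This is
#' the clean test bed for the survival estimators, complementing the
#' trajectory-level [generate_cohort()] whose induced duration frailty is
#' only approximately log-normal.
#'
#' @param n_per_group Trials per group.
#' @param hazard_ratio True hazard ratio of group `g2` versus `g1`.
#' @param baseline_hazard Baseline exponential hazard (per s).
#' @param frailty_sd True cluster frailty s.d. on the log-hazard scale.
#' @param n_clusters Number of clusters (colonies).
#' @param censor_limit Right-censoring time (s).
#' @param seed Optional integer seed.
#' @returns A tibble: `duration`, `event`, `group`, `cluster`.
#' @examples
#' generate_duration_cohort(n_per_group = 5, hazard_ratio = 2, seed = 1)
#' @export
generate_duration_cohort <- function(n_per_group = 500, hazard_ratio = 2,
                                     baseline_hazard = 1 / 1000,
                                     frailty_sd = 0, n_clusters = 10,
                                     censor_limit = 1800, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- 2 * n_per_group
  group <- factor(rep(c("g1", "g2"), each = n_per_group))
  cluster <- rep_len(rep(seq_len(n_clusters), length.out = n_per_group), n)
  z <- rnorm(n_clusters, 0, frailty_sd)
  rate <- baseline_hazard * ifelse(group == "g2", hazard_ratio, 1) *
    exp(z[cluster])
  t0 <- rexp(n, rate)
  tibble(
    duration = pmin(t0, censor_limit),
    event = t0 <= censor_limit,
    group = group,
    cluster = cluster
  )
}
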