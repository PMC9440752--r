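#' Count transversal crossings between two timed paths
#'
#' Counts the transversal intersections between two polylines, typically a
#' returning ant's trajectory and the robotic leader's outward path.  Each
#' intersecting segment pair contributes one crossing.  Degenerate
#' incidences (a vertex exactly on the other path, collinear overlap) are
#' resolved by nudging the whole reference path by a fixed oblique offset
#' of about 1e-9 of the joint extent before counting (a consistent global
#' perturbation), which makes a pass-through at a vertex count exactly
#' once, a path starting or ending on the other path count nothing there,
#' and a collinear overlap count one crossing per transversal entry.
#' Generic counts are unaffected, symmetric in the two arguments and
#' invariant under rigid motions applied to both paths.
#'
#' @param traj,reference Data frames with columns `x_mm` and `y_mm`
#'   (ordered samples); each needs at least 2 rows.
#' @returns Integer crossing count.
#' @examples
#' a <- tibble::tibble(x_mm = c(0, 10), y_mm = c(-1, 1))
#' b <- tibble::tibble(x_mm = c(0, 10), y_mm = c(1, -1))
#' count_crossings(a, b)
#' @export
count_crossings <- function(traj, reference) {
  for (p in list(traj, reference)) {
    if (!all(c("x_mm", "y_mm") %in% names(p))) {
      abort("paths need `x_mm` and `y_mm` columns")
    }
    if (nrow(p) < 2) abort("paths need at least 2 samples")
  }
  count_crossings_cpp(traj$x_mm, traj$y_mm, reference$x_mm, reference$y_mm)
}

#' Path length of a trajectory
#'
#' @param traj Data frame with `x_mm`, `y_mm`.
#' @returns Total polyline length (mm): the sum of consecutive sample
#'   distances.
#' @examples
#' path_length(tibble::tibble(x_mm = c(0, 3, 3), y_mm = c(0, 0, 4)))
#' @export
path_length <- function(traj) {
  if (nrow(traj) < 2) return(0)
  sum(sqrt(diff(traj$x_mm)^2 + diff(traj$y_mm)^2))
}

#' Time spent in each arena quadrant
#'
#' Attributes each inter-sample interval to the quadrant containing its
#' spatial midpoint (see [quadrant_of()]), so the four occupancy times sum
#' exactly to the tracked duration `t_last - t_first`.
#'
#' @param traj Data frame with `t_s`, `x_mm`, `y_mm`, time-ordered.
#' @param arena An [arena_spec()].
#' @returns A tibble with columns `quadrant` (1:4) and `time_s`.
#' @examples
#' traj <- tibble::tibble(t_s = 0:3, x_mm = c(0, 0, 400, 400),
#'                        y_mm = c(10, 10, 10, 10))
#' quadrant_times(traj, arena_spec("main"))
#' @export
quadrant_times <- function(traj, arena) {
  stopifnot(inherits(arena, "arena_spec"))
  if (nrow(traj) == 0) abort("empty trajectory")
  out <- tibble(quadrant = 1:4, time_s = 0)
  if (nrow(traj) >= 2) {
    mx <- (traj$x_mm[-1] + head(traj$x_mm, -1)) / 2
    my <- (traj$y_mm[-1] + head(traj$y_mm, -1)) / 2
    dt <- diff(traj$t_s)
    q <- quadrant_of(mx, my, arena)
    agg <- vapply(1:4, function(k) sum(dt[q == k]), numeric(1))
    out$time_s <- agg
  }
  out
}

#' Extract the censored return outcome of a trajectory
#'
#' Applies the assay's outcome rules to one return trajectory: the return
#' duration is the first time the path enters the return region
#' ([in_return_region()]); if the path never enters it the trial is
#' right-censored at the arena's censor limit (1800 s) with
#' `event = FALSE`.  Crossings of the leader's outward path (if one is
#' supplied), path length and quadrant occupancy are attached.
#'
#' @param traj Data frame with `t_s`, `x_mm`, `y_mm`; must start outside
#'   the return region (tracking begins away from the new nest).
#' @param arena An [arena_spec()].
#' @param treatment,colony Labels attached to the outcome row.
#' @param leader Optional leader path for crossing counting.
#' @param trial_id Optional identifier.
#' @param emerged Emergence flag (trials in which the ant never emerged
#'   from the new nest are aborted upstream).
#' @returns A one-row tibble: `trial_id`, `treatment`, `colony`,
#'   `duration`, `event`, `crossings`, `path_length`, `q1_s` .. `q4_s`,
#'   `emerged`.
#' @examples
#' traj <- tibble::tibble(t_s = c(0, 450, 900), x_mm = c(360, 200, 100),
#'                        y_mm = c(0, 0, 0))
#' extract_outcome(traj, arena_spec("main"), "carried", colony = 1)
#' @export
extract_outcome <- function(traj, arena, treatment, colony,
                            leader = NULL, trial_id = NA_character_,
                            emerged = TRUE) {
  stopifnot(inherits(arena, "arena_spec"))
  if (nrow(traj) == 0) abort("empty trajectory")
  inside <- in_return_region(traj$x_mm, traj$y_mm, arena)
  if (inside[1]) abort("trajectory starts inside the return region")
  hit <- which(inside)
  if (length(hit)) {
    duration <- traj$t_s[hit[1]]
    event <- TRUE
  } else {
    duration <- arena$censor_limit_s
    event <- FALSE
  }
  qt <- quadrant_times(traj, arena)
  tibble(
    trial_id = as.character(trial_id),
    treatment = as.character(treatment),
    colony = colony,
    duration = duration,
    event = event,
    crossings = if (is.null(leader)) NA_integer_ else
      count_crossings(traj, leader),
    path_length = path_length(traj),
    q1_s = qt$time_s[1], q2_s = qt$time_s[2],
    q3_s = qt$time_s[3], q4_s = qt$time_s[4],
    emerged = emerged
  )
}
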