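#' Leader-path parametrisation
#'
#' The robotic leader walks from mark A (50 mm) to mark B (350 mm) along
#' either a straight line or a sinusoid.  The programmed curve is described
#' by four parameters: `amplitude` (maximum lateral displacement from the
#' midline, mm), `distance` (straight-line start-to-finish length, mm),
#' `half_cycles` (number of lateral extrema, i.e. "peaks") and `speed`
#' (ground speed, mm/s).  The gantry logs its position every `dt` seconds
#' (0.1 s).
#'
#' Presets mirror the assay treatments: `"straight"` (A = 0, D = 300,
#' h = 0, v = 2), `"sinusoidal"` (A = 50, D = 300, h = 3, v = 2) and the
#' leader-only control replays `"control_straight"` / `"control_sinusoidal"`
#' run at the mean observed speeds 1.84 and 1.92 mm/s.
#'
#' @param amplitude Maximum lateral displacement (mm), >= 0.
#' @param distance Straight-line length (mm), > 0.
#' @param half_cycles Number of lateral extrema (non-negative integer).
#'   Coerced to 0 when `amplitude` is 0.
#' @param speed Ground speed (mm/s), > 0.
#' @param dt Sampling interval (s), > 0.
#' @param start Start point, default mark A `c(50, 0)`.
#' @returns A `leader_path_spec` list.
#' @examples
#' leader_path_spec(preset = "sinusoidal")
#' @export
leader_path_spec <- function(amplitude = 0, distance = 300, half_cycles = 0,
                             speed = 2, dt = 0.1, start = c(50, 0),
                             preset = NULL) {
  if (!is.null(preset)) {
    preset <- arg_match(preset, c(
      "straight", "sinusoidal",
      "control_straight", "control_sinusoidal"
    ))
    p <- switch(preset,
      straight           = list(0, 300, 0, 2),
      sinusoidal         = list(50, 300, 3, 2),
      control_straight   = list(0, 300, 0, 1.84),
      control_sinusoidal = list(50, 300, 3, 1.92)
    )
    amplitude <- p[[1]]; distance <- p[[2]]
    half_cycles <- p[[3]]; speed <- p[[4]]
  }
  if (distance <= 0) abort("`distance` must be > 0")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  if (half_cycles < 0 || half_cycles != round(half_cycles)) {
    abort("`half_cycles` must be a non-negative integer")
  }
  if (speed <= 0) abort("`speed` must be > 0")
  if (dt <= 0) abort("`dt` must be > 0")
  if (amplitude == 0) half_cycles <- 0
  structure(list(
    amplitude = amplitude, distance = distance,
    half_cycles = as.integer(half_cycles), speed = speed, dt = dt,
    start = start, preset = preset %||% "custom"
  ), class = "leader_path_spec")
}

#' @rdname leader_path_spec
#' @param preset One of `"straight"`, `"sinusoidal"`, `"control_straight"`,
#'   `"control_sinusoidal"`; overrides the numeric arguments.
#' @export
print.leader_path_spec <- function(x, ...) {
  cat(sprintf(
    "<leader_path_spec> %s: A = %g mm, D = %g mm, h = %d, v = %g mm/s, dt = %g s\n",
    x$preset, x$amplitude, x$distance, x$half_cycles, x$speed, x$dt
  ))
  invisible(x)
}

#' Sinusoidal leader curve
#'
#' The programmed curve expressed as lateral displacement against
#' along-axis position: `y(s) = A * sin(h * pi * s / D)` for `s` in
#' `[0, D]`.  The curve vanishes at both endpoints and, for `A > 0`, has
#' exactly `h` interior extrema of magnitude `A`.  `A = 0` gives the
#' straight path.
#'
#' @param amplitude,distance,half_cycles As in [leader_path_spec()].
#' @returns A `leader_curve` list with elements `y(s)` and `dy(s)`
#'   (functions) and the parameters.
#' @examples
#' crv <- sinusoid_curve(50, 300, 3)
#' crv$y(c(50, 150, 250))
#' @export
sinusoid_curve <- function(amplitude, distance, half_cycles) {
  if (distance <= 0) abort("`distance` must be > 0")
  if (amplitude < 0) abort("`amplitude` must be >= 0")
  if (amplitude == 0) half_cycles <- 0
  k <- half_cycles * pi / distance
  structure(list(
    y = function(s) amplitude * sin(k * s),
    dy = function(s) amplitude * k * cos(k * s),
    amplitude = amplitude, distance = distance, half_cycles = half_cycles
  ), class = "leader_curve")
}

# Cumulative arc length of a leader curve on a fine along-axis grid
# (trapezoid rule, 0.01 mm spacing).
curve_arc_table <- function(curve, ds = 0.01) {
  s <- seq(0, curve$distance, by = ds)
  if (tail(s, 1) < curve$distance) s <- c(s, curve$distance)
  speed <- sqrt(1 + curve$dy(s)^2)
  n <- length(s)
  seglen <- diff(s) * (speed[-1] + speed[-n]) / 2
  list(s = s, arc = c(0, cumsum(seglen)))
}

#' Arc length of a leader curve
#'
#' @param curve A [sinusoid_curve()].
#' @returns Total arc length (mm), by trapezoid integration on a 0.01 mm
#'   grid.
#' @examples
#' arc_length(sinusoid_curve(0, 300, 0)) # 300
#' @export
arc_length <- function(curve) {
  stopifnot(inherits(curve, "leader_curve"))
  tail(curve_arc_table(curve)$arc, 1)
}

#' Sample a leader curve as a constant-speed timed path
#'
#' Reparametrises the curve by arc length (numeric inversion of the
#' cumulative-arc-length table by linear interpolation) and samples it at
#' constant ground speed `spec$speed`, one sample every `spec$dt` seconds,
#' starting at mark A.  The final sample is placed exactly at the curve end
#' (mark B for D = 300), so the total duration equals
#' `arc_length / speed` to within one `dt`.
#'
#' @param curve A [sinusoid_curve()]; defaults to the curve implied by
#'   `spec`.
#' @param spec A [leader_path_spec()].
#' @returns A tibble with columns `t_s`, `x_mm`, `y_mm` and attribute
#'   `source = "leader"`.
#' @examples
#' path <- sample_timed_path(spec = leader_path_spec(preset = "straight"))
#' head(path)
#' @export
sample_timed_path <- function(curve = NULL, spec) {
  stopifnot(inherits(spec, "leader_path_spec"))
  if (is.null(curve)) {
    curve <- sinusoid_curve(spec$amplitude, spec$distance, spec$half_cycles)
  }
  tab <- curve_arc_table(curve)
  total <- tail(tab$arc, 1)
  step <- spec$speed * spec$dt
  arc_pts <- seq(0, total, by = step)
  if (total - tail(arc_pts, 1) > 1e-9) arc_pts <- c(arc_pts, total)
  s_pts <- approx(tab$arc, tab$s, xout = arc_pts, ties = "ordered")$y
  out <- tibble(
    t_s = arc_pts / spec$speed,
    x_mm = spec$start[1] + s_pts,
    y_mm = spec$start[2] + curve$y(s_pts)
  )
  attr(out, "source") <- "leader"
  attr(out, "spec") <- spec
  out
}

#' @rdname sample_timed_path
#' @export
leader_path <- function(spec) sample_timed_path(spec = spec)
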