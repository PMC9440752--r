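#' Arena geometry for the homing assay
#'
#' Builds the canonical coordinate frame of the experimental arena.  The
#' origin sits at the old-nest entrance, +x runs along the arena midline
#' towards the new nest, +y to the left; all distances are millimetres and
#' times seconds.  Reference marks lie on the +x midline: mark A at 50 mm
#' (start of the programmed leader path), mark B at 350 mm (its end), and
#' the placement mark at 360 mm where the new-nest entrance sits and where
#' carried ants are released.  The old nest is housed under a 120 x 120 mm
#' Petri dish centred on the origin; an ant is deemed to have returned once
#' it comes within `return_radius_mm` (50 mm) of that dish footprint.
#'
#' Two presets are provided: `"main"` (1134 x 980 mm, the tracked-gantry
#' arena) and `"filmed"` (900 mm along the travel axis x 600 mm, the smaller
#' arena used for overhead filming).  The origin is offset from the old-nest
#' end wall by `origin_offset_mm` so the full arena rectangle is
#' `x in [-offset, width - offset]`, `y in [-height/2, height/2]`.
#'
#' @param preset `"main"` or `"filmed"`; ignored when explicit dimensions
#'   are supplied.
#' @param width_mm,height_mm Arena dimensions (mm); width is the midline
#'   (travel) axis.
#' @param origin_offset_mm Distance (mm) from the old-nest end wall to the
#'   origin.
#' @param dish_side_mm Side (mm) of the square Petri dish covering the old
#'   nest.
#' @param return_radius_mm Return criterion: distance (mm) to the dish
#'   footprint at or below which the ant has returned.
#' @param tracking_start_radius_mm Radius (mm) around the new nest inside
#'   which auto-tracking could not see the ant.
#' @param censor_limit_s Trial abort limit (s) for the return run; returns
#'   not observed by then are right-censored.
#' @param emergence_limit_s Abort limit (s) for emergence from the new nest.
#' @returns An object of class `arena_spec`: a validated list with the
#'   fields above plus `mark_a`, `mark_b`, `placement_mark`,
#'   `new_nest_size_mm` (76 x 51 mm) and the bounding box `xlim`, `ylim`.
#' @examples
#' arena <- arena_spec("main")
#' arena$placement_mark
#' in_return_region(c(0, 300), c(0, 0), arena)
#' @export
arena_spec <- function(preset = c("main", "filmed"),
                       width_mm = NULL, height_mm = NULL,
                       origin_offset_mm = 150,
                       dish_side_mm = 120,
                       return_radius_mm = 50,
                       tracking_start_radius_mm = 30,
                       censor_limit_s = 1800,
                       emergence_limit_s = 1200) {
  if (is.null(width_mm) != is.null(height_mm)) {
    abort("supply both `width_mm` and `height_mm`, or neither")
  }
  if (is.null(width_mm)) {
    preset <- arg_match(preset)
    dims <- switch(preset,
      main   = c(1134, 980),
      filmed = c(900, 600)
    )
    width_mm <- dims[1]
    height_mm <- dims[2]
    if (preset == "filmed") origin_offset_mm <- 100
  } else {
    preset <- "custom"
  }
  check_positive <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
      abort(paste0("`", what, "` must be a single positive number"))
    }
  }
  check_positive(width_mm, "width_mm")
  check_positive(height_mm, "height_mm")
  check_positive(dish_side_mm, "dish_side_mm")
  check_positive(return_radius_mm, "return_radius_mm")
  check_positive(tracking_start_radius_mm, "tracking_start_radius_mm")
  check_positive(censor_limit_s, "censor_limit_s")
  check_positive(emergence_limit_s, "emergence_limit_s")
  check_positive(origin_offset_mm, "origin_offset_mm")

  arena <- structure(list(
    preset = preset,
    width_mm = width_mm,
    height_mm = height_mm,
    origin_offset_mm = origin_offset_mm,
    dish_side_mm = dish_side_mm,
    mark_a = c(50, 0),
    mark_b = c(350, 0),
    placement_mark = c(360, 0),
    new_nest_size_mm = c(76, 51),
    tracking_start_radius_mm = tracking_start_radius_mm,
    return_radius_mm = return_radius_mm,
    censor_limit_s = censor_limit_s,
    emergence_limit_s = emergence_limit_s,
    xlim = c(-origin_offset_mm, width_mm - origin_offset_mm),
    ylim = c(-height_mm / 2, height_mm / 2)
  ), class = "arena_spec")

  if (origin_offset_mm < dish_side_mm / 2) {
    abort("`origin_offset_mm` must leave the old-nest dish inside the arena")
  }
  marks_x <- c(arena$mark_a[1], arena$mark_b[1], arena$placement_mark[1])
  if (any(marks_x >= arena$xlim[2])) {
    abort("arena too short: midline marks at 50/350/360 mm fall outside it")
  }
  if (dish_side_mm / 2 > height_mm / 2) {
    abort("arena too narrow for the old-nest dish")
  }
  arena
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf(
    "<arena_spec> %s: %g x %g mm, origin at old-nest entrance (offset %g mm)\n",
    x$preset, x$width_mm, x$height_mm, x$origin_offset_mm
  ))
  cat(sprintf(
    "  marks at x = 50 / 350 / 360 mm; dish %g mm, return radius %g mm\n",
    x$dish_side_mm, x$return_radius_mm
  ))
  cat(sprintf(
    "  censor limit %g s, emergence limit %g s\n",
    x$censor_limit_s, x$emergence_limit_s
  ))
  invisible(x)
}

#' Convert an arena to/from a plain configuration list
#'
#' `arena_config()` returns a plain named list (suitable for YAML/JSON
#' round-tripping); `as_arena()` rebuilds the validated `arena_spec` from
#' such a list, either `list(preset = "main")` or explicit dimensions.
#'
#' @param arena An [arena_spec()] object.
#' @param config A named list as produced by `arena_config()`.
#' @returns `arena_config()`: a named list; `as_arena()`: an `arena_spec`.
#' @examples
#' identical(as_arena(arena_config(arena_spec("filmed"))), arena_spec("filmed"))
#' @export
arena_config <- function(arena) {
  stopifnot(inherits(arena, "arena_spec"))
  list(
    preset = arena$preset,
    width_mm = arena$width_mm,
    height_mm = arena$height_mm,
    origin_offset_mm = arena$origin_offset_mm,
    dish_side_mm = arena$dish_side_mm,
    return_radius_mm = arena$return_radius_mm,
    tracking_start_radius_mm = arena$tracking_start_radius_mm,
    censor_limit_s = arena$censor_limit_s,
    emergence_limit_s = arena$emergence_limit_s
  )
}

#' @rdname arena_config
#' @export
as_arena <- function(config) {
  if (inherits(config, "arena_spec")) {
    return(config)
  }
  if (is.character(config) && length(config) == 1) {
    return(arena_spec(config))
  }
  stopifnot(is.list(config))
  known <- c(
    "preset", "width_mm", "height_mm", "origin_offset_mm", "dish_side_mm",
    "return_radius_mm", "tracking_start_radius_mm", "censor_limit_s",
    "emergence_limit_s"
  )
  bad <- setdiff(names(config), known)
  if (length(bad)) {
    abort(paste0("unknown arena config keys: ", paste(bad, collapse = ", ")))
  }
  preset <- config$preset
  args <- config[setdiff(names(config), "preset")]
  if (!is.null(preset) && preset %in% c("main", "filmed")) {
    base <- arena_config(arena_spec(preset))
    args <- utils::modifyList(base[setdiff(names(base), "preset")], args)
    out <- do.call(arena_spec, args)
    out$preset <- preset
    out
  } else {
    do.call(arena_spec, args)
  }
}

#' Return-region predicate
#'
#' An ant has returned once its Euclidean distance to the Petri-dish
#' footprint covering the old nest (a `dish_side_mm` square centred on the
#' origin) is at most `return_radius_mm`.  The boundary is closed: a point
#' exactly at the threshold counts as returned.
#'
#' @param x,y Point coordinates (mm), vectorised.
#' @param arena An [arena_spec()].
#' @returns Logical vector.
#' @examples
#' in_return_region(c(0, 110, 300), c(0, 0, 0), arena_spec("main"))
#' @export
in_return_region <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_spec"), length(x) == length(y))
  half <- arena$dish_side_mm / 2
  dx <- pmax(abs(x) - half, 0)
  dy <- pmax(abs(y) - half, 0)
  sqrt(dx^2 + dy^2) <= arena$return_radius_mm
}

#' Quadrant partition around the placement mark
#'
#' The arena is divided into four quadrants by the vertical and horizontal
#' lines through the placement mark (the point where ants are released,
#' 360 mm along the midline), labelled clockwise 1-4 starting from the
#' upper quadrant on the old-nest side: 1 = old-nest side, y > 0;
#' 2 = far side, y > 0; 3 = far side, y < 0; 4 = old-nest side, y < 0.
#' Points on a dividing line are assigned to the lower-numbered adjacent
#' quadrant (the placement mark itself to quadrant 1).
#'
#' @inheritParams in_return_region
#' @returns Integer vector with values in 1:4.
#' @examples
#' quadrant_of(c(0, 400, 400, 0), c(10, 10, -10, -10), arena_spec("main"))
#' @export
quadrant_of <- function(x, y, arena) {
  stopifnot(inherits(arena, "arena_spec"), length(x) == length(y))
  x0 <- arena$placement_mark[1]
  y0 <- arena$placement_mark[2]
  dx <- x - x0
  dy <- y - y0
  q <- integer(length(x))
  upper <- dy >= 0 # y = y0 divider resolves upward (quadrants 1/2)
  q[upper & dx <= 0] <- 1L # x = x0 divider, upper: quadrant 1
  q[upper & dx > 0] <- 2L
  q[!upper & dx >= 0] <- 3L # x = x0 divider, lower: quadrant 3
  q[!upper & dx < 0] <- 4L
  q
}
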