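#' Kaplan-Meier estimate of the return-duration survival function
#'
#' Product-limit estimator (via [survival::survfit()]) of the probability
#' of not yet having returned by time t, with right censoring at the trial
#' limit; at tied times deaths precede censorings, and the curve is
#' right-continuous with drops only at event times.  A time-0 row with
#' survival 1 is prepended per group.
#'
#' @param data A data frame of trials.
#' @param duration,event Columns (tidy-eval): duration (s) and event flag.
#' @param group Optional grouping column; one curve per level.
#' @returns A tibble of class `km_curve`: `group` (if supplied), `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`.
#' @examples
#' d <- tibble::tibble(duration = c(2, 3, 4, 4, 5),
#'                     event = c(TRUE, FALSE, TRUE, TRUE, FALSE))
#' km_estimate(d, duration, event)
#' @export
km_estimate <- function(data, duration, event, group = NULL) {
  time <- dplyr::pull(data, {{ duration }})
  status <- as.numeric(dplyr::pull(data, {{ event }}))
  if (length(time) < 1) abort("empty sample")
  g_quo <- enquo(group)
  has_group <- !quo_is_null(g_quo)
  if (has_group) {
    g <- factor(dplyr::pull(data, !!g_quo))
    sf <- survival::survfit(
      survival::Surv(time, status) ~ g,
      data = data.frame(time = time, status = status, g = g)
    )
    strata <- rep(names(sf$strata), sf$strata)
    out <- tibble(
      group = sub("^g=", "", strata),
      time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
      n_censor = sf$n.censor, survival = sf$surv
    )
    zero <- tibble(
      group = sub("^g=", "", names(sf$strata)),
      time = 0, n_risk = as.numeric(table(g)), n_event = 0,
      n_censor = 0, survival = 1
    )
    out <- arrange(bind_rows(zero, out), .data$group, .data$time)
  } else {
    sf <- survival::survfit(survival::Surv(time, status) ~ 1)
    out <- tibble(
      time = c(0, sf$time), n_risk = c(length(time), sf$n.risk),
      n_event = c(0, sf$n.event), n_censor = c(0, sf$n.censor),
      survival = c(1, sf$surv)
    )
  }
  class(out) <- c("km_curve", class(out))
  out
}

#' Kernel-smoothed hazard of the return duration
#'
#' Smooths the Nelson-Aalen hazard increments (events / at-risk at each
#' event time) with an Epanechnikov kernel:
#' `h(t) = sum_i K_b(t - t_i) * dH(t_i)` with
#' `K_b(u) = 0.75 / b * (1 - (u/b)^2)` for `|u| <= b`.  The estimate is
#' nonnegative by construction and identically zero when there are no
#' events.  The default bandwidth is 0.3 times the observed duration
#' range.
#'
#' @inheritParams km_estimate
#' @param bandwidth Kernel bandwidth (s), > 0; default
#'   `0.3 * diff(range(duration))`.
#' @param grid_n Number of evaluation points over `[0, max(duration)]`.
#' @returns A tibble of class `hazard_curve`: `group` (if supplied),
#'   `time`, `hazard`; the bandwidth is attached as an attribute.
#' @examples
#' d <- tibble::tibble(duration = rexp(50, 1 / 300),
#'                     event = TRUE)
#' h <- hazard_estimate(d, duration, event, bandwidth = 200)
#' @export
hazard_estimate <- function(data, duration, event, group = NULL,
                            bandwidth = NULL, grid_n = 256) {
  time <- dplyr::pull(data, {{ duration }})
  status <- as.numeric(dplyr::pull(data, {{ event }}))
  if (length(time) < 1) abort("empty sample")
  bandwidth <- bandwidth %||% (0.3 * diff(range(time)))
  if (bandwidth <= 0) abort("`bandwidth` must be > 0")
  grid <- seq(0, max(time), length.out = grid_n)

  smooth_one <- function(tt, st) {
    sf <- survival::survfit(survival::Surv(tt, st) ~ 1)
    keep <- sf$n.event > 0
    ti <- sf$time[keep]
    dH <- sf$n.event[keep] / sf$n.risk[keep]
    if (!length(ti)) return(rep(0, length(grid)))
    u <- outer(grid, ti, "-") / bandwidth
    K <- 0.75 / bandwidth * pmax(1 - u^2, 0)
    drop(K %*% dH)
  }

  g_quo <- enquo(group)
  if (!quo_is_null(g_quo)) {
    g <- factor(dplyr::pull(data, !!g_quo))
    out <- purrr::map_dfr(levels(g), function(lv) {
      hz <- smooth_one(time[g == lv], status[g == lv])
      tibble(group = lv, time = grid, hazard = hz)
    })
  } else {
    hz <- smooth_one(time, status)
    out <- tibble(time = grid, hazard = hz)
  }
  attr(out, "bandwidth") <- bandwidth
  class(out) <- c("hazard_curve", class(out))
  out
}
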