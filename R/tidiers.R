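#' Tidy a Cox or frailty fit
#'
#' Broom-style accessors: `tidy()` returns one row per coefficient with
#' the hazard ratio and Wald test; `glance()` returns a one-row model
#' summary.
#'
#' @param x A [cox_fit()] or [frailty_fit()] object.
#' @param ... Unused.
#' @returns A tibble.
#' @examples
#' d <- generate_duration_cohort(n_per_group = 40, hazard_ratio = 2, seed = 1)
#' tidy(cox_fit(d, duration, event, group))
#' @export
tidy.cox_fit <- function(x, ...) {
  z <- x$coef / x$se
  tibble(
    term = x$terms,
    estimate = x$coef,
    hazard_ratio = exp(x$coef),
    std_error = x$se,
    statistic = z,
    p_value = 2 * pnorm(-abs(z))
  )
}

#' @rdname tidy.cox_fit
#' @export
tidy.frailty_fit <- tidy.cox_fit

#' @rdname tidy.cox_fit
#' @export
glance.cox_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_event = x$n_event,
    loglik = unname(x$loglik["final"]),
    loglik_null = unname(x$loglik["null"]),
    iterations = x$iter,
    converged = x$converged
  )
}

#' @rdname tidy.cox_fit
#' @export
glance.frailty_fit <- function(x, ...) {
  tibble(
    n = x$n,
    n_event = x$n_event,
    theta = x$theta,
    theta_multiplier = x$theta_multiplier,
    loglik_integrated = unname(x$loglik["integrated"]),
    loglik_cox = unname(x$loglik["cox"]),
    iterations = x$iter,
    converged = x$converged
  )
}
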