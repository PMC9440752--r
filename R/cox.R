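# Cox partial-likelihood machinery (Breslow tie handling).
#
# The same core serves the plain proportional-hazards fit and the
# colony-frailty fit: a design matrix U holds the fixed-effect columns and,
# for the frailty model, one indicator column per cluster whose coefficients
# are the random intercepts, ridge-penalised by 1/theta^2.  The frailty
# variance is profiled on a Laplace approximation to the integrated partial
# likelihood, the approach of mixed-effects Cox software.

# Partial log likelihood, gradient and observed information at `coef`.
# `pen` is the diagonal ridge penalty (0 for fixed effects).
cox_pl_parts <- function(coef, time, status, U, pen) {
  n <- length(time)
  m <- ncol(U)
  ord <- order(time, decreasing = TRUE)
  ts <- time[ord]
  st <- status[ord]
  Us <- U[ord, , drop = FALSE]
  eta <- drop(Us %*% coef)
  emax <- max(eta)
  w <- exp(eta - emax)
  cumw <- cumsum(w)
  cumUw <- apply(Us * w, 2, cumsum)
  if (m == 1) cumUw <- matrix(cumUw, ncol = 1)
  # row-wise outer products w_i * u_i u_i', stored as n x m^2
  ii <- rep(seq_len(m), times = m)
  jj <- rep(seq_len(m), each = m)
  U2 <- Us[, ii, drop = FALSE] * Us[, jj, drop = FALSE] * w
  cumU2 <- apply(U2, 2, cumsum)
  if (m^2 == 1) cumU2 <- matrix(cumU2, ncol = 1)

  ev <- st == 1
  ev_times <- unique(ts[ev]) # descending
  # risk-set size for each event time: number of sorted times >= t
  r <- findInterval(-ev_times, -ts)
  d <- as.numeric(table(factor(ts[ev], levels = ev_times)))
  sum_ev_U <- colSums(Us[ev, , drop = FALSE])

  loglik <- sum(eta[ev]) - sum(d * (log(cumw[r]) + emax))
  bar <- cumUw[r, , drop = FALSE] / cumw[r]
  grad <- sum_ev_U - colSums(d * bar)
  t1 <- matrix(colSums(d * cumU2[r, , drop = FALSE] / cumw[r]), m, m)
  t2 <- crossprod(bar * sqrt(d))
  info <- t1 - t2

  list(
    loglik = loglik,
    penalized = loglik - 0.5 * sum(pen * coef^2),
    grad = grad - pen * coef,
    info = info + diag(pen, m),
    info_unpen = info
  )
}

# Newton-Raphson maximisation of the (penalised) partial likelihood to
# gradient norm < tol, with step halving.
cox_newton <- function(time, status, U, pen = rep(0, ncol(U)),
                       init = rep(0, ncol(U)), tol = 1e-8, max_iter = 50) {
  coef <- init
  parts <- cox_pl_parts(coef, time, status, U, pen)
  converged <- FALSE
  monotone <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    step <- tryCatch(solve(parts$info, parts$grad), error = function(e) NULL)
    if (is.null(step)) {
      monotone <- TRUE
      break
    }
    new_coef <- coef + step
    new_parts <- cox_pl_parts(new_coef, time, status, U, pen)
    halvings <- 0
    while (new_parts$penalized < parts$penalized - 1e-12 && halvings < 20) {
      step <- step / 2
      new_coef <- coef + step
      new_parts <- cox_pl_parts(new_coef, time, status, U, pen)
      halvings <- halvings + 1
    }
    coef <- new_coef
    parts <- new_parts
    if (max(abs(coef[pen == 0])) > 15) {
      monotone <- TRUE
      break
    }
    if (sqrt(sum(parts$grad^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(
    coef = coef, parts = parts, iter = iter,
    converged = converged, monotone = monotone
  )
}

cox_design <- function(data, duration, event, group) {
  time <- dplyr::pull(data, {{ duration }})
  status <- as.numeric(dplyr::pull(data, {{ event }}))
  g <- dplyr::pull(data, {{ group }})
  if (any(time <= 0)) abort("durations must be positive")
  if (!all(status %in% c(0, 1))) abort("`event` must be logical or 0/1")
  if (sum(status) < 1) abort("need at least one event")
  if (is.character(g)) g <- factor(g)
  if (is.factor(g) && nlevels(droplevels(g)) < 2) {
    abort("`group` needs at least two levels")
  }
  mm <- model.matrix(~g)
  X <- mm[, -1, drop = FALSE]
  colnames(X) <- sub("^g", "", colnames(X))
  list(time = time, status = status, X = X)
}

#' Cox proportional-hazards fit for censored return durations
#'
#' Maximises the Breslow-tie partial likelihood by Newton-Raphson (to
#' gradient norm below `1e-8`) and reports, per covariate level, the log
#' hazard ratio, the hazard ratio, its standard error from the inverse
#' observed information, and the Wald z and p value.  Complete separation
#' (monotone likelihood) is flagged with a warning rather than returned
#' silently.
#'
#' @param data A data frame of trials.
#' @param duration,event,group Columns (tidy-eval): positive duration (s),
#'   event flag (`TRUE` = returned, `FALSE` = censored), and the treatment
#'   covariate (factor, character or numeric).
#' @returns A `cox_fit` object; see [tidy()] and [glance()] methods.
#' @examples
#' d <- generate_duration_cohort(n_per_group = 60, hazard_ratio = 2, seed = 1)
#' tidy(cox_fit(d, duration, event, group))
#' @export
cox_fit <- function(data, duration, event, group) {
  des <- cox_design(data, {{ duration }}, {{ event }}, {{ group }})
  m <- ncol(des$X)
  fit <- cox_newton(des$time, des$status, des$X)
  if (fit$monotone) {
    warn("monotone partial likelihood (complete separation); estimates unreliable")
  }
  null_ll <- cox_pl_parts(rep(0, m), des$time, des$status, des$X,
                          rep(0, m))$loglik
  vcov <- tryCatch(solve(fit$parts$info), error = function(e) {
    matrix(NA_real_, m, m)
  })
  se <- sqrt(pmax(diag(vcov), 0))
  structure(list(
    terms = colnames(des$X),
    coef = fit$coef,
    se = se,
    loglik = c(null = null_ll, final = fit$parts$loglik),
    n = length(des$time),
    n_event = sum(des$status),
    iter = fit$iter,
    converged = fit$converged,
    monotone = fit$monotone
  ), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf(
    "<cox_fit> n = %d, events = %d, partial loglik = %.3f\n",
    x$n, x$n_event, x$loglik["final"]
  ))
  print(tidy(x))
  invisible(x)
}

#' Cox fit with a log-normal colony frailty
#'
#' Extends [cox_fit()] with a cluster-level (colony) random intercept on
#' the log hazard, `b_j ~ N(0, theta^2)`.  For fixed `theta` the random
#' intercepts are estimated jointly with the treatment effect by Newton
#' steps on the ridge-penalised partial likelihood; `theta` itself is then
#' profiled on the Laplace approximation to the integrated partial
#' likelihood,
#' `l(theta) = PPL(beta, b) - log det(I + theta^2 H_bb) / 2`,
#' with `H_bb` the information block of the random intercepts.  The
#' boundary `theta = 0` is admissible and reproduces the plain Cox fit.
#'
#' @inheritParams cox_fit
#' @param cluster Column identifying the cluster (colony) of each trial;
#'   at least two clusters are needed to estimate `theta`.
#' @param theta Optional fixed frailty standard deviation; `NULL`
#'   (default) estimates it.
#' @param theta_max Upper end of the profiled `theta` range.
#' @returns A `frailty_fit` object with elements `theta` (frailty s.d.),
#'   `theta_multiplier` (`exp(theta)`), `frailty` (per-cluster intercepts)
#'   and `loglik` including the integrated value.
#' @examples
#' d <- generate_duration_cohort(n_per_group = 50, hazard_ratio = 2,
#'                               frailty_sd = 0.5, n_clusters = 10, seed = 2)
#' f <- frailty_fit(d, duration, event, group, cluster)
#' f$theta
#' @export
frailty_fit <- function(data, duration, event, group, cluster,
                        theta = NULL, theta_max = 3) {
  des <- cox_design(data, {{ duration }}, {{ event }}, {{ group }})
  cl <- factor(dplyr::pull(data, {{ cluster }}))
  q <- nlevels(cl)
  p <- ncol(des$X)
  if (q < 2 && is.null(theta)) {
    warn("single cluster: frailty s.d. fixed at 0")
    theta <- 0
  }
  Z <- matrix(0, length(cl), q, dimnames = list(NULL, levels(cl)))
  Z[cbind(seq_along(cl), as.integer(cl))] <- 1
  U <- cbind(des$X, Z)

  base <- cox_newton(des$time, des$status, des$X)
  base_ll <- base$parts$loglik

  warm <- c(base$coef, rep(0, q)) # warm start carried across profile steps
  fit_at <- function(th) {
    pen <- c(rep(0, p), rep(1 / th^2, q))
    f <- cox_newton(des$time, des$status, U, pen, init = warm)
    if (f$converged) warm <<- f$coef
    f
  }
  profile_ll <- function(th) {
    f <- fit_at(th)
    Hbb <- f$parts$info_unpen[p + seq_len(q), p + seq_len(q), drop = FALSE]
    f$parts$penalized -
      0.5 * determinant(diag(q) + th^2 * Hbb, logarithm = TRUE)$modulus
  }

  if (is.null(theta)) {
    opt <- optimise(profile_ll, c(1e-4, theta_max), maximum = TRUE,
                    tol = 1e-3)
    if (opt$objective > base_ll + 1e-8) {
      theta <- opt$maximum
      loglik_int <- as.numeric(opt$objective)
    } else {
      theta <- 0
      loglik_int <- base_ll
    }
  } else if (theta > 0) {
    loglik_int <- as.numeric(profile_ll(theta))
  } else {
    loglik_int <- base_ll
  }

  if (theta > 0) {
    f <- fit_at(theta)
    vcov <- tryCatch(solve(f$parts$info), error = function(e) {
      matrix(NA_real_, p + q, p + q)
    })
    coef <- f$coef[seq_len(p)]
    se <- sqrt(pmax(diag(vcov)[seq_len(p)], 0))
    b <- f$coef[p + seq_len(q)]
    ppl <- f$parts$penalized
    iter <- f$iter
    converged <- f$converged
  } else {
    vcov <- tryCatch(solve(base$parts$info), error = function(e) {
      matrix(NA_real_, p, p)
    })
    coef <- base$coef
    se <- sqrt(pmax(diag(vcov)[seq_len(p)], 0))
    b <- rep(0, q)
    ppl <- base_ll
    iter <- base$iter
    converged <- base$converged
  }

  structure(list(
    terms = colnames(des$X),
    coef = coef,
    se = se,
    theta = theta,
    theta_multiplier = exp(theta),
    frailty = tibble(cluster = levels(cl), intercept = b),
    loglik = c(
      cox = base_ll, penalized = ppl, integrated = loglik_int
    ),
    n = length(des$time),
    n_event = sum(des$status),
    iter = iter,
    converged = converged
  ), class = "frailty_fit")
}

#' @export
print.frailty_fit <- function(x, ...) {
  cat(sprintf(
    "<frailty_fit> n = %d, events = %d, frailty sd = %.3f (exp = %.3f)\n",
    x$n, x$n_event, x$theta, x$theta_multiplier
  ))
  print(tidy(x))
  invisible(x)
}

#' Likelihood-ratio comparison of nested Cox fits
#'
#' Compares a plain [cox_fit()] with the corresponding [frailty_fit()] on
#' the same data: twice the log-likelihood difference (integrated partial
#' likelihood for the frailty fit) referred to a chi-square with 1 degree
#' of freedom, the convention used when testing a single variance
#' component.  (A 50:50 chi-square mixture reference would be more
#' accurate at the `theta = 0` boundary and makes the df = 1 version
#' conservative.)
#'
#' @param fit_without,fit_with Nested fits on identical data (the first
#'   without the frailty term).
#' @returns A one-row tibble: `statistic`, `df`, `p_value`.
#' @examples
#' d <- generate_duration_cohort(n_per_group = 50, hazard_ratio = 2, seed = 3)
#' lrt_compare(cox_fit(d, duration, event, group),
#'             frailty_fit(d, duration, event, group, cluster))
#' @export
lrt_compare <- function(fit_without, fit_with) {
  ll0 <- fit_loglik(fit_without)
  ll1 <- fit_loglik(fit_with)
  if (fit_without$n != fit_with$n || fit_without$n_event != fit_with$n_event) {
    abort("fits are not nested on identical data")
  }
  stat <- max(0, 2 * (ll1 - ll0))
  tibble(
    statistic = stat,
    df = 1,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE)
  )
}

fit_loglik <- function(fit) {
  if (inherits(fit, "frailty_fit")) {
    unname(fit$loglik["integrated"])
  } else if (inherits(fit, "cox_fit")) {
    unname(fit$loglik["final"])
  } else {
    abort("expected a `cox_fit` or `frailty_fit`")
  }
}
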