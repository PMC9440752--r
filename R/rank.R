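#' Kruskal-Wallis test with Holm-adjusted pairwise post hocs
#'
#' Rank test for a difference in location among k treatment groups
#' (midranks for ties, tie-corrected H statistic, chi-square reference
#' with k - 1 df), followed by all pairwise two-sample Wilcoxon rank-sum
#' tests with Holm step-down adjustment across the k(k-1)/2 comparisons.
#' Pairwise tests are exact when both groups have at most `exact_max`
#' observations and no ties straddle the pair, otherwise the normal
#' approximation with tie correction is used.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval): the response (e.g. crossing
#'   counts) and the treatment label.
#' @param exact_max Per-group size at or below which exact pairwise
#'   p values are attempted.
#' @returns A `rank_test` list: `statistic` (H), `df`, `p_value`, and
#'   `pairwise`, a tibble with `group1`, `group2`, `p_raw`, `p_holm`.
#' @examples
#' d <- tibble::tibble(v = c(1, 3, 2, 8, 9, 7, 4, 5, 6),
#'                     g = rep(c("a", "b", "c"), each = 3))
#' kruskal_wallis(d, v, g)
#' @export
kruskal_wallis <- function(data, value, group, exact_max = 10) {
  v <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  g <- droplevels(g)
  if (nlevels(g) < 2) abort("need at least two groups")
  if (any(table(g) == 0)) abort("every group needs observations")
  if (length(unique(v)) == 1) {
    # fully tied data: the tie-corrected statistic is 0/0; no evidence
    kt <- list(statistic = c(`Kruskal-Wallis chi-squared` = 0),
               parameter = c(df = nlevels(g) - 1), p.value = 1)
  } else {
    kt <- kruskal.test(v, g)
  }
  lv <- levels(g)
  pairs <- utils::combn(lv, 2)
  p_raw <- apply(pairs, 2, function(pr) {
    x <- v[g == pr[1]]
    y <- v[g == pr[2]]
    use_exact <- length(x) <= exact_max && length(y) <= exact_max
    p <- suppressWarnings(
      wilcox.test(x, y, exact = use_exact, correct = TRUE)$p.value
    )
    # fully tied pairs have an undefined normal approximation: no evidence
    if (!is.finite(p)) p <- 1
    p
  })
  pairwise <- tibble(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_raw = p_raw, p_holm = holm_adjust(p_raw)
  )
  structure(list(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    pairwise = pairwise
  ), class = "rank_test")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf(
    "Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.3g\n",
    x$statistic, x$df, x$p_value
  ))
  print(x$pairwise)
  invisible(x)
}

#' Holm step-down adjustment
#'
#' Family-wise error control for a set of p values: sort ascending,
#' multiply the i-th by (m - i + 1), enforce monotonicity and cap at 1
#' (via [stats::p.adjust()]).
#'
#' @param p Numeric vector of p values in `[0, 1]`.
#' @returns Adjusted p values, elementwise at least `p`.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p values must lie in [0, 1]")
  }
  p.adjust(p, method = "holm")
}

#' Two-group linear model with residual-normality diagnostic
#'
#' Fits the two-group linear model `value ~ group` (equivalent to a
#' pooled-variance t test, df = n - 2) used for comparing the percentage
#' activity of carried versus filmed ants, and reports the Shapiro-Wilk
#' residual-normality statistic alongside.
#'
#' @param data A data frame.
#' @param value,group Columns (tidy-eval); `group` must have exactly two
#'   levels.
#' @returns A one-row tibble: `estimate` (group contrast), `statistic`
#'   (t), `df`, `p_value`, `shapiro_w`, `shapiro_p`.
#' @examples
#' d <- tibble::tibble(v = c(rnorm(15, 50, 8), rnorm(16, 48, 8)),
#'                     g = rep(c("carried", "filmed"), c(15, 16)))
#' two_group_lm(d, v, g)
#' @export
two_group_lm <- function(data, value, group) {
  v <- dplyr::pull(data, {{ value }})
  g <- droplevels(factor(dplyr::pull(data, {{ group }})))
  if (nlevels(g) != 2) abort("`group` must have exactly two levels")
  if (length(v) < 3) abort("need at least three observations")
  if (stats::var(v[g == levels(g)[1]]) == 0 &&
      stats::var(v[g == levels(g)[2]]) == 0) {
    abort("zero variance in both groups")
  }
  fit <- lm(v ~ g)
  sm <- summary(fit)$coefficients
  sw <- shapiro.test(stats::residuals(fit))
  tibble(
    estimate = sm[2, "Estimate"],
    statistic = sm[2, "t value"],
    df = fit$df.residual,
    p_value = sm[2, "Pr(>|t|)"],
    shapiro_w = unname(sw$statistic),
    shapiro_p = sw$p.value
  )
}
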