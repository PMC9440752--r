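# Independent oracles used by the tests; deliberately written with
# different algorithms than the package implementations they check.

# Plain vectorised all-pairs proper-segment-intersection count (strict
# sign tests; no bounding-box pruning, no degeneracy analysis).
brute_crossings <- function(a, b) {
  ax <- a$x_mm; ay <- a$y_mm; bx <- b$x_mm; by <- b$y_mm
  n <- length(ax) - 1
  m <- length(bx) - 1
  ex <- bx[-1] - bx[-(m + 1)]
  ey <- by[-1] - by[-(m + 1)]
  cnt <- 0L
  for (i in seq_len(n)) {
    d1 <- ex * (ay[i] - by[-(m + 1)]) - ey * (ax[i] - bx[-(m + 1)])
    d2 <- ex * (ay[i + 1] - by[-(m + 1)]) - ey * (ax[i + 1] - bx[-(m + 1)])
    fx <- ax[i + 1] - ax[i]
    fy <- ay[i + 1] - ay[i]
    d3 <- fx * (by[-(m + 1)] - ay[i]) - fy * (bx[-(m + 1)] - ax[i])
    d4 <- fx * (by[-1] - ay[i]) - fy * (bx[-1] - ax[i])
    cnt <- cnt + sum(d1 * d2 < 0 & d3 * d4 < 0)
  }
  cnt
}

# Dense-resampling sign-change oracle for a curve against a straight
# reference line through (x0, y0) with direction (dx, dy): resamples the
# curve and counts strict sign changes of the signed area (zeros skipped).
sign_change_crossings <- function(curve_xy, x0, y0, dx, dy, ds = 0.01) {
  seg <- sqrt(diff(curve_xy$x_mm)^2 + diff(curve_xy$y_mm)^2)
  s <- c(0, cumsum(seg))
  grid <- seq(0, max(s), by = ds)
  gx <- approx(s, curve_xy$x_mm, grid, ties = "ordered")$y
  gy <- approx(s, curve_xy$y_mm, grid, ties = "ordered")$y
  side <- sign(dx * (gy - y0) - dy * (gx - x0))
  side <- side[side != 0]
  sum(diff(side) != 0)
}

# Mean squared net displacement of a correlated random walk after n fixed
# steps (Kareiva-Shigesada closed form), c = E[cos(turning angle)].
crw_msd_theory <- function(n, step_mm, turn_sd_rad) {
  c <- exp(-turn_sd_rad^2 / 2)
  step_mm^2 * (n * (1 + c) / (1 - c) - 2 * c * (1 - c^n) / (1 - c)^2)
}

# Conditional MLE odds ratio by coarse grid scan plus golden-section
# refinement of the conditional log likelihood (not the score equation).
oracle_cmle_or <- function(a, b, cc, d) {
  m1 <- a + b; m2 <- cc + d; n1 <- a + cc
  supp <- seq(max(0, n1 - m2), min(n1, m1))
  if (a <= min(supp)) return(0)
  if (a >= max(supp)) return(Inf)
  logdc <- lchoose(m1, supp) + lchoose(m2, n1 - supp)
  ll <- function(lp) {
    lg <- logdc + supp * lp
    a * lp - (max(lg) + log(sum(exp(lg - max(lg)))))
  }
  grid <- seq(-15, 15, length.out = 601)
  i <- which.max(vapply(grid, ll, numeric(1)))
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  exp(optimise(ll, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum)
}

# Noncentral hypergeometric tail P(A >= a | psi), for CI inversion checks.
oracle_tail_ge <- function(a, psi, m1, m2, n1) {
  supp <- seq(max(0, n1 - m2), min(n1, m1))
  lg <- lchoose(m1, supp) + lchoose(m2, n1 - supp) + supp * log(psi)
  p <- exp(lg - max(lg))
  p <- p / sum(p)
  sum(p[supp >= a])
}
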