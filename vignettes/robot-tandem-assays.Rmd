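---
title: "Models and methods behind robotandem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind robotandem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(robotandem)
```

robotandem analyses homing assays in which an ant is led by a
gantry-mounted pheromone lure (a robotic tandem-run leader) from its old
nest to a candidate new nest and then tracked on its return.  This
vignette documents the models, the conventions adopted where the assay
protocol leaves details open, the synthetic-data generator's assumptions,
and the numerical choices — in enough detail that a careful reader can
tell what the package computes and what the passing tests do and do not
establish.

## Coordinate frame and arena geometry

All geometry lives in a frame with the origin at the old-nest entrance,
+x along the arena midline towards the new nest, +y to the left;
distances are millimetres, times seconds.  The main arena is
1134 × 980 mm with the origin offset 150 mm from the near wall (the
protocol places the old nest "towards one end" without a number; 150 mm
keeps the 120 mm Petri dish and a margin inside).  Reference marks sit on
the midline at 50 mm (mark A, start of the programmed leader path),
350 mm (mark B, its end) and 360 mm (the placement mark: new-nest
entrance and carried-ant release point).  The smaller filming arena is
900 × 600 mm with the 900 mm side along the travel axis, since the
release point at 360 mm must fit with margin.

**Return criterion.**  An ant has returned when it is within 50 mm of the
Petri dish covering the old nest.  We measure distance to the *dish
footprint* (the 120 mm square), not to its centre, and treat the boundary
as closed; the protocol does not say whether "within 50 mm of the dish"
means edge or centre — the two differ by at most the 60 mm half-side —
and the edge reading matches the wording most directly.  The dish is
centred on the origin, identifying the nest centre with its entrance; at
these scales the distinction is below the tracking resolution.

**Quadrants.**  Occupancy analyses divide the arena into four quadrants
by the vertical and horizontal lines through the placement mark, labelled
clockwise 1–4 starting from the upper quadrant on the old-nest side.
Points exactly on a divider go to the lower-numbered adjacent quadrant
and the centre goes to quadrant 1; any fixed tie rule would do, but one
must be fixed for the partition property (every point maps to exactly one
quadrant) to hold literally.

## The leader path

The gantry program takes four parameters: amplitude A (maximum lateral
displacement), distance D (straight start-to-finish length), half-cycles
h (number of lateral extrema) and speed v.  The program's curve is not
published as a formula; we use

$$y(s) = A \sin(h \pi s / D), \qquad s \in [0, D],$$

the minimal curve with zero endpoints, exactly h interior extrema, and
maximum |y| = A — every property the parameter description fixes.  The
assay's treatments are A = 0, D = 300, h = 0 (straight) and A = 50,
D = 300, h = 3 (sinusoidal), both at v = 2 mm/s; leader-only control
replays run at the observed mean speeds 1.84 and 1.92 mm/s.

The gantry logs position every 0.1 s at constant ground speed, so the
curve is reparametrised by arc length: cumulative trapezoid arc length on
a 0.01 mm grid, inverted by linear interpolation, one sample per
v·dt of arc, with the final sample placed exactly at the curve end.  The
0.01 mm grid keeps the spacing error of a sampled step below 10⁻⁶ mm at
these curvatures; tests verify the polyline length against adaptive
quadrature of √(1 + y′²) to 0.1% and a relative spacing spread below
10⁻³.  Whether the physical gantry was arc-length- or time-parametrised
is not recorded; since the joystick altered only speed, never the path,
the path/speed separation is taken as the program's intent.  The final
10 mm (350 → 360 mm), where the lure was dismounted and moved by hand,
is not part of the programmed path.

## The walker model

The null walker is a correlated random walk: heading increments drawn
from N(0°, 5°), fixed 2 mm steps (about one worker body length).  Three
details the assay leaves open are fixed as follows and are configurable:

* **Time base** — 1 step/s, making the walker's 2 mm/s match the
  leader's programmed speed and the 30 min censor limit equal 1800
  steps.
* **Start and initial heading** — the placement mark, uniform heading.
* **Walls** — specular reflection.  Reflection folds the path, so the
  recorded polyline between samples straddling a bounce is shorter than
  one step; the exact path-length identity (length = steps × 2 mm) holds
  for unfolded paths and tests use wall-free configurations for it.

For synthetic ants the walk gains a homing bias: after the random turn
the heading moves a fraction w ∈ [0, 1] of the wrapped angular
difference towards the bearing of the goal (the old nest).  w = 0 is
exactly the null walker; w = 1 with zero noise walks straight to the
goal.  This linear blend is the smallest extension that nests the null
model; it is a modelling device, not a claim about ant navigation.

A consequence worth stating plainly: with these movement parameters the
*unbiased* walker already returns within the censor limit about 52% of
the time — persistence length ℓ/(1 − c) ≈ 0.5 m in a walled 1.1 m arena
over 3.6 m of travel makes the return region hard to miss.  Return
probabilities below that baseline are unreachable for any w ≥ 0, which is
why `calibrate_homing()` reports the achievable range on error rather
than extrapolating.

## Crossing statistic

The crossing count between a return trajectory and the leader's outward
path is the number of transversal intersections of the two polylines.
Generic intersections are counted by strict orientation tests, one count
per properly intersecting segment pair.  Degenerate incidences — a
sample landing exactly on the other path, collinear stretches — get
transversality semantics via a local side-change analysis: a vertex
contact counts one crossing exactly when the neighbouring samples lie
strictly on opposite sides of the other path there.  So a pass-through
at a vertex counts once, a tangential touch counts nothing, a collinear
overlap counts once per transversal entry, and a path that merely starts
or ends on the other path (the returning ant's straight line down the
midline meets the sinusoid's endpoints this way) counts nothing at the
contact.  The count is symmetric in the two paths, invariant under rigid
motions, and near-coincident intersections are *not* merged: the
statistic is a property of the polylines, with no dedup radius.

## Survival inference

Return durations are right-censored at 1800 s.  Kaplan–Meier curves and
Nelson–Aalen increments come from the survival package; the smoothed
hazard convolves the increments with an Epanechnikov kernel,
`K_b(u) = 0.75 (1 − (u/b)²)₊ / b`, default bandwidth 0.3 × the duration
range (the assay figures state no method; any reasonable kernel choice
changes only smoothness, and the bandwidth is an explicit argument).
Kernel estimates within one bandwidth of 0 or the maximum duration are
boundary-biased downward; the recovery test therefore checks a constant
hazard only over the central time range.

The Cox model is fitted in-package: Breslow tie handling, Newton–Raphson
on the partial likelihood to gradient norm < 10⁻⁸, standard errors from
the inverse observed information, Wald tests.  Breslow is adequate at
these sample sizes and tie rates; the fit is checked against
`survival::coxph(method = "breslow")` to 10⁻⁶ in the tests, and against
direct grid enumeration of the partial likelihood on a four-observation
example.  Monotone likelihoods (complete separation) are flagged with a
warning rather than returned silently.

**Colony frailty.**  Colonies are reused across trials, so the model
adds a colony-level random intercept on the log hazard,
b_c ~ N(0, θ²) — a log-normal frailty, matching the exp(θ)
interpretation of the colony effect as a hazard multiplier.  For fixed θ
the intercepts are estimated jointly with the treatment effect by Newton
steps on the ridge-penalised partial likelihood; θ is then profiled on
the Laplace approximation to the integrated partial likelihood,

$$\ell(\theta) = \mathrm{PPL}(\hat\beta, \hat b; \theta)
  - \tfrac12 \log\det(I + \theta^2 H_{bb}),$$

with H_bb the intercepts' information block.  θ = 0 is admissible and
reproduces the plain Cox fit exactly.  This integrated-likelihood route
(the one mixed-effects Cox software takes) was chosen over penalised
REML-style tuning after a null-recovery simulation: with θ = 0 truth,
REML-type criteria in the survival package placed θ̂ above 0.1 in about a
third of replicates, while the profiled Laplace likelihood shrinks to
the boundary correctly.  The likelihood-ratio comparison of the two
models reports 2Δℓ against χ²₁ — the variance component sits on the
boundary of its space under the null, so a 50:50 mixture of χ²₀ and χ²₁
would be more accurate and the df = 1 convention is conservative; df = 1
is used because it is the convention the assay's analyses report, and
comparability matters more here than the sharper reference.

## Exact and rank tests

**Fisher's exact conditional inference** is authored in-package.  The
estimate is the conditional MLE: the ψ solving `E_ψ[A] = a` under the
noncentral hypergeometric law of the first cell given both margins
(solved on the log scale to ~10⁻¹⁰); the 95% interval inverts the exact
one-sided tails at 2.5% each; the two-sided p value sums the
probabilities, at ψ = 1, of tables no more probable than the observed one
(with the same 1 + 10⁻⁷ slack `stats::fisher.test` uses, against which
all three quantities are cross-checked).  Boundary tables give 0 or ∞
with one finite confidence limit.  Solving the score and tail equations
to near machine precision matters for one subtle reason: published exact
confidence limits computed by generic root finders carry ~10⁻⁴-scale
solver error, so `reconstruct_study_table()` — which searches all 2×2
tables with the published row totals (47 robot-led, 30 carried-type) for
the one whose exact p value and confidence limits match the published
0.037 and (1.031, 10.261) — matches the p value exactly at the printed
rounding but allows ±0.002 on the limits.  The search finds exactly one
table; multiple matches would be an error, not a silent choice.

**Kruskal–Wallis** (midranks, tie correction, χ²_{k−1} reference) and
Holm's step-down adjustment delegate to `stats::kruskal.test` and
`stats::p.adjust`; post hoc pairwise comparisons are two-sample Wilcoxon
rank-sum tests, exact when both groups have ≤ 10 observations and tie
patterns allow, normal approximation with continuity and tie correction
otherwise.  A fully tied data set makes the tie-corrected H a 0/0; the
package defines H = 0, p = 1 there (no evidence).  The two-group
activity comparison is the linear model value ~ group (pooled-variance
t, df = n − 2) with a Shapiro–Wilk residual normality statistic reported
alongside, mirroring how the filmed-versus-carried quadrant-activity
check is run.

## The synthetic cohort generator

The generator emulates the assay's design so that every analysis stage
runs without any recorded tracking data.  Per cohort: ten colonies with
standard-normal effects z_c; per trial a colony is drawn, a Bernoulli
emergence gate applied (default 0.9 — roughly one abort per arm, the
order the protocol's emergence rule suggests; aborted trials carry NA
durations and are excluded from survival input), the walker simulated
from the placement mark with the arm's homing weight, and the outcome
extracted with censoring at 1800 s.  Robot-led arms carry their leader
path so crossings can be attached.  Group sizes are the study's
(16/15/16 robot-led, 15 carried, 15 control, 15 filmed, 15 + 15
simulated walkers).

**Effect sizes.**  The intended defaults — robot-led ants returning
about 64% of the time, carried about 37% — are unreachable at movement
level because of the 52% unbiased baseline documented above.  The
defaults therefore follow the intent rather than the numbers: carried
arms are unbiased walkers (w = 0), and the robot-led weight was
calibrated once, by `calibrate_homing()` with 2000 common-random-number
walkers per bisection step, to the return probability implied by the
published pooled odds ratio (3.176) at the achievable carried baseline —
target 0.775, giving w = 0.0019036.  Under a complementary-log-log
reading the same target corresponds to a hazard ratio near 2, so the
pipeline's pooled Cox contrast lands in the published direction and
magnitude order (the published 2.45 itself is not a generator target).
These weights are data-independent constants of the package; they are
not re-tuned.

**Frailty placement.**  Colony frailty multiplies the homing weight,
exp(θ z_c) with default θ = 0.35 (the order of the published
carried/control colony effect), capped at w ≤ 1 — so trajectory-level
and duration-level analyses see the same colony structure.  The induced
frailty on durations is only approximately log-normal, and with w = 0 in
carried-type arms the multiplier has nothing to act on there.  For clean
survival testing the package therefore also provides
`generate_duration_cohort()`: exponential durations (default baseline
hazard 1/1000 s⁻¹, giving ~83% events before censoring), an exact
hazard ratio between two groups, an exactly log-normal cluster frailty,
and censoring at 1800 s.  All estimator-recovery tests run on this
generator; the trajectory-level generator feeds the direction and
pipeline tests.

**What passing tests show.**  The generator reproduces the assay's
*structure* — censoring, clustering, group sizes, treatment
exchangeability (carried and control share movement parameters; the
replayed leader affects only crossing references) — but real ants pause,
loop, wall-follow, deposit and respond to pheromone, and navigate by
landmarks.  None of that is modelled; trail-mediated crossing behaviour
in particular is absent, so synthetic crossing counts are small and
treatment differences in them are geometric, not chemical.  Tests passing
on synthetic cohorts certify the estimators and the pipeline plumbing,
not any biological claim.

## Numerical conventions and degenerate inputs

* Angles wrap to [−π, π); the walker's C++ core consumes turning angles
  drawn in R, so a single `set.seed()` governs every simulation and no
  C++ RNG exists.
* Arc-length inversion: 0.01 mm grid, linear interpolation; final leader
  sample pinned to the curve end.
* Newton steps halve on penalised-likelihood decrease (≤ 20 halvings);
  |β| > 15 on an unpenalised coordinate is treated as monotone
  likelihood.
* θ is profiled on [10⁻⁴, 3] to tolerance 10⁻³ with warm-started inner
  Newton solves; a profile no better than the θ = 0 limit returns
  exactly 0.
* Trajectory files: strictly increasing time, finite decimals, `#`
  metadata comments; malformed rows are reported with their line number.
* Empty samples, all-zero tables, single clusters, zero bandwidths and
  walkers started outside the arena raise immediate errors (or, for the
  single cluster, a warning and θ = 0).

## Problem sizes

The shipped checks use 10⁴ walkers × 200 steps for the mean-squared-
displacement comparison (3-standard-error band), 200 replicates of
n = 500/group for Cox recovery, 100 such replicates for null-frailty
recovery, every 2×2 table with row margins ≤ 12 (7812 informative
tables) for the conditional-MLE oracle sweep, 100 seeded walkers against
the sinusoidal path for the crossing oracle, and 100 seeded cohorts for
the direction check.  These sizes put Monte-Carlo error well below each
test's acceptance band while keeping the whole suite a few minutes long.

## Known limitations

* The homing bias is phenomenological; no landmark learning, trail
  laying or pheromone response is modelled, and the filmed arm differs
  from carried only by its arena.
* The Laplace profile for θ is an approximation; its accuracy degrades
  with very few clusters or very few events per cluster (the shipped
  configurations use 8–10 clusters).
* Crossing counts treat the tracked polyline as the path; no smoothing,
  gap interpolation beyond linearity, or excision of the tracker's
  30 mm blind zone near the new nest is applied.
* The two-sided exact p value uses probability-mass ordering; other
  orderings (e.g. central) give different but equally defensible
  values.
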