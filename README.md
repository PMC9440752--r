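# robotandem

Simulation and analysis of robot-led tandem-running homing assays in ants.

In a tandem run, one *Temnothorax* worker leads a single nest-mate to a
goal, pausing while the follower memorises landmarks.  A gantry-mounted
pheromone lure can stand in for the leading ant: it walks a programmed
straight or sinusoidal path from the old nest to a candidate new nest, and
the follower is then tracked on its way home.  The analytical questions
such an assay raises are the substance of this package:

* Do led ants return home faster and more often than ants merely carried
  to the same spot?  Return durations are right-censored at the 30 min
  trial limit, so this is survival analysis: Kaplan–Meier curves,
  kernel-smoothed hazards, and a Cox proportional-hazards model
  `h_i(t) = h_0(t) exp(x_i'β + b_{c(i)})` with a colony-level random
  intercept `b_c ~ N(0, θ²)` (a log-normal shared frailty), compared with
  the fixed-effects model by a likelihood-ratio test on the integrated
  partial likelihood.
* Do the odds of returning at all differ?  Fisher's exact conditional
  inference on the pooled 2×2 table: the conditional-MLE odds ratio ψ̂
  solves `E_ψ[A] = a` under the noncentral hypergeometric distribution of
  the first cell given both margins, with an exact tail-inversion
  confidence interval and a probability-mass two-sided p value.
* Do returning ants follow the leader's outward path?  The crossing
  statistic counts transversal intersections between the return
  trajectory and the leader's programmed polyline; treatments are
  compared by a Kruskal–Wallis test with Holm-adjusted pairwise post
  hocs.
* How would a naive walker behave?  The null movement model is a
  correlated random walk — 2 mm steps, Gaussian turning angles with 5°
  s.d. — whose mean squared net displacement follows the closed form
  `E[R_n²] = ℓ²[n(1+c)/(1−c) − 2c(1−cⁿ)/(1−c)²]` with mean turning-angle
  cosine `c = exp(−σ²/2)`.

No raw tracking data accompany the assay, so the package ships a
synthetic-cohort generator: treatment archetypes with the study's group
sizes, a tunable homing bias grafted onto the correlated random walk,
colony frailty, emergence failures and censoring, all reproducible from a
single seed.  Every analysis stage is exercised end to end against it.

## Worked example

```r
library(robotandem)

coh <- generate_cohort(seed = 42)
out <- dplyr::filter(coh$outcomes, emerged)

dplyr::summarise(dplyr::group_by(out, treatment),
                 n = dplyr::n(), returned = sum(event),
                 proportion = round(mean(event), 2), .groups = "drop")
#>   treatment      n returned proportion
#> 1 carried       13        8       0.62
#> 2 cleaned       15        9       0.6
#> 3 control       15        8       0.53
#> 4 filmed        15        7       0.47
#> 5 simulated     30       12       0.4
#> 6 sinusoidal    13       10       0.77
#> 7 straight      13       11       0.85
```

Pool the robot-led arms against the carried-type arms and fit the
censored return durations:

```r
surv <- dplyr::filter(out, treatment != "filmed", treatment != "simulated")
surv$pooled <- ifelse(surv$treatment %in% c("straight", "sinusoidal", "cleaned"),
                      "robot-led", "carried")

tidy(cox_fit(surv, duration, event, pooled))
#>   term      estimate hazard_ratio std_error statistic p_value
#> 1 robot-led    0.446         1.56     0.311      1.43   0.152
```

At this seed the robot-led ants' instantaneous return rate is 1.56 times
the carried ants' — the direction the generator builds in, not
significant at one cohort's sample size (69 emerged trials).  Adding the
colony frailty and comparing:

```r
frail <- frailty_fit(surv, duration, event, group = pooled, cluster = colony)
c(frail$theta, frail$theta_multiplier)
#> [1] 0 1
lrt_compare(cox_fit(surv, duration, event, pooled), frail)
#>   statistic    df p_value
#> 1         0     1       1
```

The estimated colony effect is nil (θ̂ = 0, multiplier exp(θ̂) = 1), as it
should be: the default generator spreads trials over ten colonies with a
modest frailty.  Finally the pooled odds of returning:

```r
tab <- with(surv, c(sum(pooled == "robot-led" & event),
                    sum(pooled == "robot-led" & !event),
                    sum(pooled == "carried" & event),
                    sum(pooled == "carried" & !event)))
fisher_exact(tab)
#>   estimate conf_low conf_high p_value
#> 1     2.02    0.654      6.39   0.199
```

`reproduce_report(seed = 42, dir = "report")` runs the whole pipeline —
survival and hazard figures, the crossing boxplot, the proportions table,
the Holm matrix and the pooled exact test — and writes a manifest with
the seed and configuration hash.

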