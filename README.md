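# egpvar

Variance decomposition of male lifetime reproductive success into
extra-group and within-group paternity components.

## The problem

In socially monogamous species with extra-pair (here: extra-group) mating,
a male's genetic reproductive success splits into within-group paternity
(WGP — young sired with his own social female) and extra-group paternity
(EGP — young sired elsewhere). The *opportunity for selection* is the
mean-standardized variance in reproductive success,
`I = var(RS) / mean(RS)^2`, an upper bound on how strong selection can be.
`egpvar` is for behavioural and evolutionary ecologists who have (or want
to emulate) long-term individual-based paternity data and ask: how much of
the opportunity for selection flows through extra-group siring, at which
ages, and does it exceed the variance the social mating system alone would
generate?

The core identities, for lifetime measures and their age-specific
expansions:

```
var(LRS)  =  var(LEGP) + var(LWGP) + 2 cov(LEGP, LWGP)
var(LRS)  =  Σ_i var(RS_i) + Σ_{j>i} 2 cov(RS_i, RS_j)        (zero-padded)
```

with every term further split into EGP/WGP components, standardized either
by squared lifetime means (additive method, longevity included) or within
ages among survivors (independent method, longevity removed). Confidence
intervals are bias-corrected accelerated (BCa) bootstrap intervals,
resampling whole males. A mate-level decomposition splits each pathway's
variance into number-of-mates, fecundity-per-mate and paternity-share
contributions with an exact remainder. A calibrated individual-based
simulator (geometric-like lifespans, dominance acquisition, hump-shaped
siring curves, shared log-normal frailty, cuckoldry) makes the whole
pipeline runnable and testable with no external data.

## Worked example

```r
library(egpvar)
pop <- simulate_population(simulator_config(n_males = 237, seed = 1))
lifetime_partition(pop$life)
#>   component     term    level age_i age_j  mean  raw   n standardized percent
#> 1       EGP variance lifetime    NA    NA 0.717 1.66 237        0.459    21.0
#> 2       WGP variance lifetime    NA    NA 1.186 3.16 237        0.873    39.9
#> 3   EGPxWGP     2cov lifetime    NA    NA    NA 3.11 237        0.858    39.2
#> 4        RS variance lifetime    NA    NA 1.903 7.93 237        2.189   100.0
#> 5     RS_ap variance lifetime    NA    NA 1.743 4.93 237        1.623   100.0
```

Reading: in this simulated cohort of 237 males the standardized variance in
lifetime genetic RS (the opportunity for selection) is 2.19, of which 21%
comes from variance in lifetime EGP, 40% from WGP, and 39% from their
positive covariance — males siring more within-group young also sire more
extra-group young, mostly because both totals grow with longevity. The
social measure's standardized variance is 1.62, so extra-group paternity
raises the opportunity for selection by a factor
`variance_ratio(2.189, 1.623) ≈ 1.35` here.

BCa intervals (2,000 replicates, resampling males, re-standardizing inside
each resample):

```r
decorate_table(lifetime_partition(pop$life), pop$life, B = 2000, seed = 1)
#>   component standardized lower upper
#> 1       EGP        0.459 0.351 0.637
#> 2       WGP        0.873 0.688 1.120
#> 3   EGPxWGP        0.858 0.661 1.112
#> 4        RS        2.189 1.763 2.731
#> 5     RS_ap        1.623 1.324 2.005
```

The RS and RS_ap intervals overlap, so by the non-overlap rule the genetic
and social opportunities for selection do not differ significantly in this
cohort. Age-specific tables come from `additive_partition()` /
`independent_partition()` on `build_age_matrix()` output, and
`check_decomposition()` verifies the exact additivity of every table.

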