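---
title: "Partitioning the opportunity for selection via extra-group paternity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning the opportunity for selection via extra-group paternity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egpvar)
```

## The question and the quantities

In socially monogamous but genetically promiscuous species, a male's
genetic reproductive success (RS) splits into young sired within his own
social group (within-group paternity, WGP) and young sired in other groups
(extra-group paternity, EGP). The *opportunity for selection* is the
mean-standardized variance in reproductive success,
$I = \mathrm{var}(RS)/\overline{RS}^2$ — an upper bound on the strength of
selection. Whether extra-group siring inflates this opportunity beyond what
the social mating system alone would produce is the question this package
quantifies.

Because lifetime RS is a sum, its variance partitions exactly:

$$\mathrm{var}(LRS) = \mathrm{var}(LEGP) + \mathrm{var}(LWGP)
  + 2\,\mathrm{cov}(LEGP, LWGP).$$

With males observed annually, each lifetime total is itself a sum over age
classes, and `additive_partition()` expands the lifetime variance into
age-specific variances, within-age EGP–WGP covariances, and between-age
covariances (including the cross-component terms
$2\,\mathrm{cov}(EGP_i, WGP_j)$, emitted per ordered pair $i \neq j$).
This "additive" convention zero-pads males who died before the oldest
observed age, which is what makes the terms sum exactly to
$\mathrm{var}(LRS)$ — longevity differences are *part of* the partition.
The complementary "independent" convention (`independent_partition()`)
instead treats post-mortem ages as missing and partitions the per-age
variance among survivors only, free of longevity.

A third axis compares genetic RS with social ("apparent") reproduction
RS_ap — the young produced by a male's social female(s) regardless of sire.
The ratio of the standardized variances, `variance_ratio()`, measures how
much extra-group paternity raises the opportunity for selection over the
social mating system.

## Standardization conventions

All (co)variances are reported raw and standardized. The conventions
mirror how the two partitions are used:

* lifetime and additive-method terms divide by the squared *lifetime* mean
  (genetic terms by $\overline{LRS}^2$, apparent terms by
  $\overline{LRS_{ap}}^2$), so standardized terms still sum to the
  standardized total;
* independent-method terms divide by the squared *within-age* mean of the
  corresponding measure among survivors (genetic terms by the age-specific
  mean RS, apparent by the age-specific mean RS_ap).

Standardization is scale-free: multiplying every count by a positive
constant leaves every standardized value unchanged (this is a tested
invariant). A zero mean with standardization requested is an explicit
error at the lifetime level, and an `NA` (undefined, never zero) within an
age. Ages with fewer than two survivors likewise propagate `NA`.

The variance denominator is the sample convention $n-1$ by default, with a
`denom = "n"` switch; every additivity identity holds under either, as the
identities are linear in the (co)variance operator.

## Reading data, age conventions

`read_records()` ingests a comma- or tab-delimited long table, one row per
male and age class. Ages in years are binned with `bin_age_class()`:
nearest integer (halves round up), ages from 8 months to 1.5 years map to
class 1 (reproductive maturity starts around 8 months), and all ages of 12
years or more pool into class 12 (old males are rare, so per-age estimates
above 11 would rest on a handful of individuals). Non-dominant males carry
`rs_ap = 0` by definition — a male without a breeding position has no
social female — and validation enforces this, along with integer
non-negative counts and at most one row per male and age. A male's
zero-offspring years need no explicit rows: any age before his last
recorded age is zero-filled, which is exactly the distinction between
"zero" (alive, sired nothing) and "missing" (dead) that separates the two
padding modes.

## The synthetic population

`simulate_population()` generates male life histories so every downstream
stage runs, and is tested, without field data. The generative model:

1. **Lifespan**: survival from age $a$ to $a+1$ with probability
   `survival_p[a]` (default a constant 0.81, capped at 16 years), giving a
   left-skewed, geometric-like lifespan with mode 1 and mean about 5.1
   years.
2. **Dominance**: an age of first dominance is drawn on ages 1–6 (mean
   about 1.9, mode 2), with a small probability of never qualifying;
   males whose draw exceeds their lifespan die subordinate, so roughly a
   quarter of males never hold a breeding position.
3. **Siring**: a dominant male of frailty $f$ sires
   $EGP_a \sim \mathrm{Pois}(f\,\lambda^{E}_a)$ and
   $WGP_a \sim \mathrm{Pois}(f\,\lambda^{W}_a)$ per age. The default
   curves are Gaussian bumps on age (EGP peaking at age 6, WGP at age 5)
   with near-zero rates at age 1, scaled so the expected lifetime totals
   are 0.87 extra-group and 1.30 within-group young. Subordinates sire at
   a tiny extra-group rate (default 0.03/year, roughly 2% of all young).
4. **Frailty**: $f$ is log-normal with mean one and log-sd
   `frailty_sd = 0.7`, shared by both pathways. Together with lifespan
   heterogeneity this produces the over-dispersed, zero-heavy lifetime
   distributions and a positive lifetime EGP–WGP covariance; longevity
   alone (no frailty) already makes the covariance positive, since both
   totals accumulate over the same dominant years.
5. **Social brood**: the apparent count $RS_{ap,a}$ is Poisson with the
   territory brood rate; by default it is drawn *independently* of the
   male's own WGP (the decomposition never uses a WGP ≤ RS_ap coupling).
   In the optional `coupled` mode the male's WGP is instead a binomial
   thinning of his own brood with success probability
   `1 - cuckoldry_prob` (default 0.44, the share of social young sired by
   extra-group males); coupled mode with zero cuckoldry and zero
   extra-group rates makes genetic and apparent totals identical male by
   male, which is how that invariant is tested.

The calibration targets are population summaries, chosen once: mean
lifespan ≈ 5.1 years, mean lifetime RS ≈ 2.2 with ≈ 40% sired extra-group,
and ≈ 47% of males with zero lifetime RS. The frailty scale is a
compromise: a log-sd near 1.0 would push the zero fraction to exactly
0.47 but produces implausibly extreme maximum lifetime RS (hundreds),
so 0.7 was fixed, landing the zero fraction near 0.46 with a realistic
tail. What the generator does **not** emulate: territory geography and
helper effects, female-side processes, year (cohort) effects on rates,
and any pedigree structure — so passing tests demonstrate the
*arithmetic* of the decomposition and the *statistical* behaviour of the
intervals, not fidelity to any particular wild population.

## BCa bootstrap conventions

Confidence intervals come from a bias-corrected accelerated nonparametric
bootstrap written in the package (`bca_interval()`). Conventions that
matter for reproducibility, fixed and documented:

* the resampling unit is the **male** — a resample keeps each male's whole
  life history intact, and every statistic (including the mean in a
  standardization denominator) is recomputed inside each resample;
* bias correction $z_0 = \Phi^{-1}(\#\{\theta^*_b < \hat\theta\}/B)$
  counts replicates **strictly below** the observed value; ties are
  excluded (with discrete data this choice changes $z_0$, so it is fixed);
* acceleration $a$ uses the jackknife skewness formula
  $a = \sum d_i^3 / (6 (\sum d_i^2)^{3/2})$ with
  $d_i = \bar\theta_{(\cdot)} - \theta_{(i)}$;
* quantiles are order statistics with linear interpolation (R's default
  type 7);
* if every replicate falls on one side of the observed value, $z_0$ is
  undefined and the plain percentile interval is returned with a warning
  and a `fallback` flag; a degenerate replicate distribution yields a
  point interval;
* with $z_0 = a = 0$ the interval reduces algebraically to the percentile
  interval (tested).

Two values are called significantly different when their intervals do not
overlap; touching intervals count as overlapping. This is a conservative
rule — non-overlap at 95% is stricter than a 5% test — and it is the only
significance machinery the pipeline uses.

A known limitation, reproduced side by side with the reference
implementation in the `boot` package: for heavy-tailed standardized
variance functionals at a few hundred males, BCa intervals undercover
(about 86–87% instead of 95% for a Poisson–log-normal population with
log-sd 0.75). The coverage test therefore uses a mildly overdispersed
Poisson–log-normal generator (log-sd 0.3), whose standardized variance has
the closed form $1/\lambda + e^{\sigma^2} - 1$, where coverage is close to
nominal (~93% over 500 datasets of 200 males). Interval widths for the
heavy-tailed study-scale case should be read with that caveat.

## Mate-number decomposition

For males successful through both pathways, each pathway total factors as
$T = M \cdot N \cdot P$: number of mates, mean offspring per mate, and
paternity share. The package defines $P = T / (M N)$ — the male's overall
share of his mates' offspring — rather than a per-mate mean share, because
only this definition makes the factorization an exact identity (a per-mate
mean of ratios does not reproduce $T$ when broods differ). The variance of
$T$ across males is expanded to first order around the means
($\mathrm{var}(M)$, $\mathrm{var}(N)$, $\mathrm{var}(P)$ terms and the
three pairwise covariance terms) plus an **explicit remainder** carrying
all higher moments, so the emitted terms always total $\mathrm{var}(T)$
exactly; the classic first-order approximation (no remainder) sits behind
`first_order = TRUE` for comparison with literature values. Cross-pathway
rows report the covariance of the two totals and of the two mate numbers.
When real dam identities are unavailable the summaries can be fabricated
from lifetime totals by `simulate_mates()`, which is labelled synthetic and
only guarantees consistency with the totals.

## Problem sizes and runtime choices

The test suite exercises the additivity identities on 100 simulated
datasets of 50–500 males, brute-force covariance oracles on up to 6 males
and 3 ages, coverage on 500 datasets of 200 males with 1,999 replicates,
and calibration on 5,000-male populations; these sizes make the arithmetic
checks exact and keep Monte-Carlo error small relative to the loose
calibration bands. The bootstrap default is `B = 10000` for final
interval estimation; pipeline runs and examples use 2,000, which is ample
for 95% endpoints to the reported precision.

## Worked example

```{r example, eval = FALSE}
pop <- simulate_population(simulator_config(n_males = 237, seed = 1))
life <- pop$life
lifetime_partition(life)
mat <- build_age_matrix(pop$records, "additive")
tab <- additive_partition(mat)
check_decomposition(tab)       # all TRUE: the terms reassemble var(LRS)
decorate_table(lifetime_partition(life), life, B = 2000, seed = 1)
```

## Limitations

* The simulator's defaults are calibration choices, not estimates — no
  parametric model of age-specific rates was fitted to data.
* Between-age covariances are only defined under the additive convention;
  the independent method deliberately emits none (pairwise-complete
  between-age covariances among survivors are not provided).
* Generalized linear mixed models of the drivers of lifetime reproduction
  (longevity, age of first dominance), Bateman gradients and selection
  gradients on phenotypic traits are out of scope; standard mixed-model
  software handles the former directly on the `aggregate_lifetime()`
  output.
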