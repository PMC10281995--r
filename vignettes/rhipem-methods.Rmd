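---
title: "Reconstructing cumulative head impact exposure: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing cumulative head impact exposure: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhipem)
```

## The exposure-reconstruction model

Helmet accelerometer studies report, per level of play and (for high
school and college) per position, the average number of head impacts a
player sustains in a season and the mean per-hit linear and rotational
accelerations. `rhipem` organizes these summaries into a
position-exposure matrix (PEM), the football analogue of an occupational
job-exposure matrix, and uses it to score careers retrospectively.

### Pooling rule

Each PEM cell is a pooled mean over contributing studies, each study's
central value weighted in proportion to its sample size:

$$\bar v_{\ell,p,m} \;=\; \frac{\sum_i n_i v_i}{\sum_i n_i}$$

over studies $i$ reporting metric $m$ for position $p$ at level $\ell$.
Means and medians are pooled identically (the source literature reports
both; `central_kind` is kept as provenance only), and a missing sample
size is an error rather than a default weight, because the weighting *is*
the construction and a silent default would bias cells. Studies that
report aggregate values for a position group (for example "non-speed"
covering the offensive and defensive lines) are expanded to one record
per member position before pooling, each carrying the group's value and
sample size.

Three conventions complete the matrix:

* **The overall row.** A level's `overall` cell is taken from team-wide
  (overall-scoped) reports when any exist; only when a level and metric
  has exclusively position-specific reports is the overall cell pooled
  across all of them, sample-size weighted. This choice keeps a published
  overall row intact when a matrix is rebuilt from per-cell study data —
  the overall row of a printed matrix is generally *not* the pooled mean
  of its position rows, since different studies contribute to each — while
  still realizing the across-positions pool whenever no direct overall
  report exists.
* **Imputation.** Position cells with no direct study data are filled
  from the level's overall cell and flagged `imputed`. All youth cells
  are of this kind (no youth study reports positions), as are a few
  collegiate rotational cells.
* **Level mapping.** No helmet-sensor data exist above college, so
  semi-professional and professional seasons resolve to the collegiate
  row (recorded in `mapped_from_level`). Positions outside the matrix
  vocabulary — kickers, punters, unknown — resolve to the level's
  overall row, the only defensible default, and are flagged in
  provenance. The 10 g minimum-impact threshold common to the source
  studies is carried as metadata only; inputs are already season
  summaries, so no runtime filtering applies.

### Cumulative indices

For a career of $y$ seasons with PEM values $h_n$ (hits/season), $g_n$
(g/hit) and $r_n$ (rad/s²/hit) for the level and position played in
season $n$:

$$\mathrm{CHII} = \sum_{n=1}^{y} h_n, \qquad
  \mathrm{CHII\text{-}G} = \sum_{n=1}^{y} h_n g_n, \qquad
  \mathrm{CHII\text{-}R} = \sum_{n=1}^{y} h_n r_n.$$

A season played at two positions contributes the mean of the two
*per-position annual indices* (the per-position product is formed first,
then averaged), not the product of averaged hits and averaged intensity.
Equal weights are used within a season: informant-reported percent time
by position proved unreliable in pilot work for this kind of study, so it
is deliberately unsupported. More than two positions in a season is
accepted with a warning and averaged equally. Seasons are integer years;
fractional participation is out of scope.

Effect estimates downstream are reported per scaled unit — per 1,000
hits, per 10,000 g, per 1,000,000 rad/s² — so `compute_indices()` also
returns those scaled views; scaling happens before model fitting so
coefficients are directly in reporting units.

### NFT burden

Neuropathology is summarized by the sum of semi-quantitative (0–3)
neurofibrillary-tangle scores over the 11 brain regions implicated in
CTE, range 0–33. The complete-case rule applies: a donor missing any
region has no burden score (`NA`) and is excluded from burden models; no
imputation is performed.

## The association battery

Each exposure measure (informant concussion count, non-speed vs speed
position, years of play, CHII, CHII-G, CHII-R) is fitted *separately* —
the cumulative measures are far too collinear for a joint model — in an
age-at-death-adjusted regression: logistic for CTE status (absent vs
present) and for severity (low vs high stage, CTE-positive subset),
linear for NFT burden (complete panels). Key numerical and inferential
choices:

* Wald 95% intervals on the log-odds, exponentiated for reporting
  (profile likelihood out of scope). Logistic fits converge to a
  relative tolerance of 1e-10 with a 100-iteration cap; constant
  exposures raise a degenerate-design error and complete/quasi-complete
  separation is detected and reported rather than returning a divergent
  estimate.
* BIC is computed from its definition $k\ln n - 2\ell$ (cross-checked
  against `stats::BIC` in the tests) and differences are read with the
  conventional evidence bands: below 2 none, 2–6 positive, 6–10 strong,
  above 10 very strong.
* The ROC AUC is the Mann–Whitney concordance (ties count half), with a
  seeded percentile bootstrap CI. Differences in discriminative power
  between two models scored on the same donors use a *paired* bootstrap:
  donors resampled with replacement, both AUCs recomputed per replicate
  (2,000 by default), two-sided percentile p-value of the difference
  against zero. A studentized or asymptotic alternative would also be
  defensible; the percentile form was chosen for transparency.
* Cross-validation error is the Brier score — mean squared difference
  between predicted probability and the 0/1 outcome over the held-out
  folds — with simple (unstratified) random folds of size within one,
  seeded so stratified variants can be compared later.
* Multiplicity is handled with the Bonferroni-adjusted level 0.0083;
  AUC/CV companions are computed for exposures passing a 0.05 screen,
  mirroring the practice of reporting model-performance companions only
  for significant exposures.

## The synthetic cohort generator

Brain-donor data of this kind are restricted, so the package ships a
seeded generator whose defaults emulate the structure of a large
football brain-donor case series; it is how the pipeline is tested and
how the statistical machinery is validated by parameter recovery.

* **Careers.** Age of first exposure and duration are truncated normals
  (first exposure: floor 5 y; duration: floor 1 season). The location
  parameters (11.0 and 12.1) are set so the *realized* truncated means
  are the targets 11.3 and 12.5 years. Each season's level follows the
  donor's age that year (under 14 youth, 14–17 high school, 18–21
  college, then professional), capped at an attained highest level drawn
  from progression stops (advance past high school 0.95, past college
  0.92, semi-professional 0.087 among advancers), calibrated so the
  highest-level mix approximates the observed cohort's (45%
  professional, 4% semi-professional); donors who do not advance keep
  playing at their capped level. Primary positions follow the observed
  single-position distribution; a second position is added to a season
  with probability 0.25.
* **Outcomes.** CTE status follows a logistic model in years of play and
  age at death with an odds ratio of 1.15 per year of play; the
  intercept (−2.47) sets prevalence near the observed 71.5%. Severity
  among CTE-positive donors uses a second logistic (OR 1.14/year).
  Using years of play as the generator's driving exposure makes the
  recovery check unambiguous: the fitted duration model is exactly the
  generating model.
* **NFT burden** is linear in duration (0.47 per year) and age, with
  Gaussian noise (SD 6), rounded and clipped to 0–33, then decomposed
  over the 11 regions by drawing the burden's score units uniformly at
  random from the 33 available (11 regions × cap 3) — only the sum
  enters the analysis, so a symmetric allocation suffices.
* **Ages at death** are truncated normal on [13, 100] (location 60.0,
  SD 20.1) floored at the age the career ended, since a donor cannot die
  mid-career; the floor shifts the marginal mean by roughly +0.4 years,
  which the tests allow for.
* **Concussion counts** are lognormal (median 20, log-SD 1.8), matching
  the observed heavy tail (informant reports range into the thousands).
  The observed SD far exceeds the mean, and the lognormal is a modeling
  choice, not an observed distribution.
* **Missingness**: with probability 0.18 a donor loses 1–3 random NFT
  regions (70/20/10%), reproducing the ~18% incomplete-panel rate.
* **Reproducibility.** Each concern — study values, careers, outcomes,
  NFT, concussions, missingness — draws from its own named RNG stream
  derived from the master seed, so toggling one feature does not shift
  the others, and cohorts are bit-reproducible from their YAML sidecar
  (written at full floating-point precision for exactly this reason).

### What passing tests do and do not show

The generator's outcome models are the same families the analysis fits,
so parameter recovery, null calibration and coverage checks validate the
*statistical machinery*, not the biology: they show the pipeline
estimates what it claims to estimate when its assumptions hold. Real
donor data differ in ways the generator does not emulate — convenience
sampling of heavily exposed donors, secular changes in play style, era
effects in the helmet-sensor extrapolation, exposure measurement error
from informant recall, comorbid neuropathology — so green tests here say
nothing about effect sizes in any real cohort.

## Problem sizes and test design

The test suite exercises the pooling and index computations against
independent brute-force oracles (explicit loops over studies and
season-position pairs) at 1e-12 relative tolerance; the published worked
career is checked to one decimal, the precision at which its values are
printed. Simulation-based checks use cohorts of 500–10,000 donors:
coverage of the generating odds ratio over 100 cohorts of 5,000,
p-value uniformity under the null over 500 cohorts of 500
(Kolmogorov–Smirnov), and Monte-Carlo error bounds elsewhere, sizes
chosen to keep the full suite under a few minutes while leaving the
binomial/KS bounds comfortably informative.

## Known limitations

* The PEM inherits everything the helmet-sensor literature does not
  measure: special-teams exposure, sub-threshold (<10 g) impacts,
  era-specific play styles, and any systematic helmet-sensor bias.
* Professional exposure is a collegiate extrapolation.
* The severity model conditions on CTE-positive status; with small
  cohorts the subset can be too small to fit, and the grid runner skips
  it with a logged reason rather than failing.
* The level-progression model is a coarse age-bracket approximation;
  youth/high-school-only shares run above the emulated cohort's because
  short careers truncate before the college bracket.
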