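---
title: "Screening careless respondents and measuring what it changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening careless respondents and measuring what it changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A fraction of survey respondents answer without processing item content.
Even at the 8–12% prevalence typical of student samples, these careless
(insufficient-effort) responses distort the psychometric properties a
validation study reports: they attenuate inter-item correlations, depress
reliability, flatten factor loadings — especially of reverse-coded items —
and, when the carelessness is acquiescent (agreeing regardless of content),
they shift item intercepts and break scalar measurement invariance between
attentive and careless respondents.

`carescreen` implements the comparative workflow for quantifying these
effects on a multidimensional Likert instrument: simulate or read a
response matrix, flag careless respondents, run the full psychometric
battery *in parallel* on the unscreened and screened samples, and rank
items by their vulnerability with the Composite Sensitivity Index

$$\mathrm{CSI}_j = |\Delta M_j| + |\Delta r_j| + |\Delta\lambda_j|,$$

the unweighted sum of the absolute between-sample differences in item mean
(recoded metric), corrected item-total correlation, and standardized factor
loading. A z-scored variant (each component standardized across items
before summation) checks that rankings are not an artifact of component
scale; agreement between the two is summarized with Spearman's rho and
Kendall's tau-b.

The reference instrument is a 37-item sustainable-development-awareness
battery: 36 scored items on three correlated factors (economy 13, society
9, environment 14), six reverse-coded items at presentation positions 1, 8,
10, 24, 31 and 35, and an instructed-response item at position 26 that
directs respondents to choose the "Neutral" category.

## The synthetic-data generator

`sim_config()` / `assemble_study()` generate study cohorts with known
ground truth. Attentive respondents follow a graded congeneric factor
model: factor scores $\theta \sim N(0, \Phi)$ with unit variances and
correlations 0.5 by default; latent item responses
$y_{ij} = \lambda_j \theta_{f(j)} + \varepsilon_{ij}$ with
$\mathrm{Var}(\varepsilon) = 1 - \lambda_j^2$; categories cut at fixed
thresholds. Default true loadings are fixed, not drawn: standard items
evenly spaced over 0.52–0.72 and reverse items at 0.30, for a grand mean
near 0.57 (the magnitude a screened sample of this kind of attitude scale
typically shows, and deliberately low for reverse items, whose observed
loadings are usually weak).

Two generator choices deserve explanation:

* **Agreement-skewed thresholds.** Thresholds sit at the normal quantiles
  of cumulative probabilities (0.05, 0.15, 0.40, 0.75) — category shares
  5/10/25/35/25% and an attentive item mean near 3.7. A symmetric choice
  would put every attentive item mean exactly at the midpoint, and then
  acquiescent contamination would shift standard and reverse items by
  numerically identical amounts; the hallmark asymmetry of careless
  responding (mean shifts concentrated in reverse-coded items) would
  vanish by construction. Attitude scales are in practice agree-skewed, so
  the skew is the realistic default, not a tuning knob.
* **The skew follows content.** Reverse-coded items are generated on the
  construct-aligned metric with the same thresholds and then reflected
  onto the presentation scale. On the presentation metric they therefore
  have sign-flipped loadings and disagree-skewed distributions, exactly as
  a negatively worded item behaves; analytic recoding realigns them.

Careless respondents are content-blind archetypes that govern the *entire*
battery, including the instructed item — a careless respondent does not
wake up for the attention check:

* `acquiescent` — every item drawn from the top two categories with
  probabilities 0.52/0.48 (the agree/strongly-agree split observed among
  attention-check failers, renormalized after dropping the few
  disagreement failures);
* `random_uniform` — uniform over all categories (passes the check with
  probability 1/5: the single-indicator blind spot);
* `midpoint_straightliner` — the required midpoint everywhere (always
  passes the check, maximal longstring);
* `fixed_straightliner` — one random category repeated across the battery;
* `late_onset` — attentive up to a configurable onset position, then an
  archetype (acquiescent by default).

The default mixture is 70% acquiescent, 15% random, 10% fixed
straightliner and 5% late onset at 11.33% prevalence — a stand-in chosen
once, since real archetype composition is only observable among check
failers. A single master seed drives counter-based per-respondent
substreams, so adding rows never perturbs existing rows' draws.

Optional criterion blocks emulate a follow-on battery (a 19-item 0..10
scale and a 9-item 1..7 scale). Their `latent_corr` parameter is the
correlation between the block latent and the *equally weighted composite*
of the focal factors — the quantity criterion validity is about — with the
implied per-factor correlation derived internally; score-level
correlations then come out attenuated below the latent value by both
scales' unreliability.

What the generator does **not** emulate: gradual within-person attention
drift (only the abrupt `late_onset` form), item-content heterogeneity
beyond the loading spread, response styles of attentive respondents
(midpoint/extreme preferences), position effects such as elevated
sensitivity of the item right after the attention check, and any
demographic structure. Passing tests therefore show the pipeline measures
what the model puts in — not that real data behave this simply.

## Screening indicators

* **Instructed item (primary flag):** any response other than the required
  category.
* **Longstring:** maximum run of identical consecutive responses, on raw
  presentation values over the full battery (focal + instructed +
  criterion items) — runs are what the respondent actually produced, so no
  recoding.
* **Even–odd consistency:** per factor, means of the odd- and
  even-position items (positions within the factor's own list); per
  respondent, the Pearson correlation of the (odd, even) pairs across
  factors, stepped up by Spearman–Brown $r_{sb} = 2r/(1+r)$ and reported
  as $1 - r_{sb}$, so higher = more inconsistent, range 0–2. The raw
  half-correlation is floored at $-0.999$ to guard the pole at $-1$, and a
  respondent with zero-variance half-means (a pure straightliner) receives
  the maximal score 2 — invariant responding must not be rewarded with a
  missing value. The $1 - r_{sb}$ form is a convention choice: it is the
  transform that yields inconsistency scores above 1 for careless
  responders, matching how such values are reported in practice.
* **Extended flag:** instructed failure OR longstring at/above OR even-odd
  at/above cuts placed two standard deviations (denominator $n-1$) above
  the unscreened-sample means. The primary flag always implies the
  extended flag.
* **Outlier pre-screen:** before any careless screening, respondents with
  standardized totals $|z| > 4$ are removed.

## The psychometric battery

**Reliability.** Cronbach's alpha with the Feldt interval (inverting the F
distribution of $1-\alpha$ on $n-1$ and $(n-1)(k-1)$ df — the paper-trail
method for alpha intervals that needs no resampling). McDonald's omegas
come from a higher-order route: fit the design's correlated-factor model,
express the factor correlations as a second-order general factor (with
three group factors the second-order loadings have the closed form
$\gamma_1 = \sqrt{\phi_{12}\phi_{13}/\phi_{23}}$ and rotations), apply the
Schmid–Leiman transform $g_j = \lambda_j\gamma_{f(j)}$,
$s_j = \lambda_j\sqrt{1-\gamma^2}$, and compute
$\omega_h = (\sum g)^2/V$,
$\omega_t = [(\sum g)^2 + \sum_f (\sum_{j\in f} s_j)^2]/V$ with
$V = (\sum g)^2 + \sum_f(\sum s)^2 + \sum\psi$. Other decompositions of
the general factor exist (e.g. a direct bifactor fit); printed omegas from
other toolkits are therefore comparable only in pattern, not digit for
digit.

**CFA.** Plain maximum likelihood on the unbiased covariance matrix:
minimize
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}) - \log|S| - p$
for the simple-structure model $\Sigma = \Lambda\Phi\Lambda' + \Psi$,
marker identification (first loading per factor fixed at 1);
$\chi^2 = (n-1)F$ at the optimum. Robust (sandwich-corrected) estimation
is deliberately out of scope — with 5-category items, plain-ML fit indices
differ slightly from robust-scaled ones, so only estimator-insensitive
quantities should be compared across software. Numerical choices:

* $\Phi$ is parameterized by its Cholesky factor, so the implied
  covariance is positive-definite by construction; residual variances are
  bounded below at 0.001, and a solution at that bound is reported as a
  Heywood warning.
* Start values: free loadings from item/marker sd ratios, factor variances
  $0.49\,\mathrm{Var}(\text{marker})$, factor correlations 0.3, residuals
  at half the item variance.
* Optimization: quasi-Newton (`nlminb`) with analytic gradients, polished
  by L-BFGS-B cycles until the projected gradient norm falls below
  $10^{-5}$, with up to three jittered restarts under a fixed jitter seed;
  the best solution by objective value is kept. (The gradient is checked
  against numerical differentiation in the test suite's oracle runs.)
* CFI/TLI use the independence baseline with free variances and means;
  RMSEA's 90% interval inverts the noncentral chi-square; SRMR is the
  root-mean-square standardized residual over the lower triangle
  *including* the diagonal, with unbiased variances — one of several SRMR
  dialects, fixed so golden values stay stable.
* CR and AVE per factor come from the standardized solution:
  $\mathrm{CR} = (\sum\lambda)^2/[(\sum\lambda)^2+\sum(1-\lambda^2)]$,
  $\mathrm{AVE} = \sum\lambda^2/k$.

**Invariance.** Configural, metric and scalar multigroup models with mean
structure (intercepts free at configural/metric, factor means fixed at
zero except the second group's at scalar). The multigroup discrepancy is
the Wishart-convention sum $\sum_g (n_g-1)F_g$, and the multigroup RMSEA
denominator uses $df \times (N - G)$. A step is supported when
$\Delta\mathrm{CFI} \ge -0.010$ and $\Delta\mathrm{RMSEA} \le 0.015$; the
chi-square difference test is reported alongside. The df ladder for a
$p$-item, $m$-factor design increases by $p - m$ at the metric step and
again at the scalar step — 1182/1215/1248 for the 36-item three-factor
instrument across two groups.

A caution surfaced by the simulations: a careless group containing
uniform-random responders and straightliners carries a bipolar
"acquiescence-contrast" covariance structure of its own (standard items
vs reverse-coded items), and metric equality with the attentive group can
then genuinely fail; a purely acquiescent careless group retains metric
invariance while clearly breaking scalar invariance, which is the
intercept-bias signature acquiescence theory predicts.

## Impact measures

* **Nested permutation test:** the screened sample is a subset of the
  unscreened sample, so independent-sample tests do not apply to their
  mean difference. The careless-label count is reassigned without
  replacement B = 10,000 times (seed 2025 by default) and the two-sided p
  is the plain proportion of permuted $|\Delta|$ at least the observed —
  no $+1$ smoothing, because the definition is a proportion; an exhaustive
  mode enumerates all $\binom{N}{k}$ reassignments when feasible so tests
  can pin exact values.
* **Correlation comparisons:** Fisher z with the independent-samples
  formula (a documented approximation, since the samples overlap) and
  Cohen's $q = |\,\mathrm{atanh}\,r_1 - \mathrm{atanh}\,r_2|$, labelled at
  0.10/0.30/0.50 with boundaries in the lower bin.
* **Effect sizes:** Cohen's d with pooled sd, a normal-approximation
  interval, Welch's t alongside; bins 0.20/0.50/0.80, boundary to the
  lower bin. Sample-size sensitivity (`min_detectable_d`) solves the
  noncentral-t power equation by root-finding.
* **CSI / CSI-z:** as defined above; ranks break ties by presentation
  position (earlier first) for determinism. CSI-z errors on a
  zero-variance component rather than silently dropping it.

## Scale-score and data-policy conventions

Scale scores are *sums* of recoded items, never means — integer arithmetic
stays exact, and per-item conventions are explicit in the reports. Rows
with any missing, non-integer or out-of-range cell are rejected at read
time with a logged count (complete-case policy); nothing is imputed. The
instructed item is stored in every response matrix (the flag needs it) but
is structurally excluded from scores, reliability and factor models via
the design object.

## Problem sizes in the test suite

The replicate-based checks run at the study's own scale where the claim
demands it (n = 1112 with 986/126 group splits for the invariance and
contamination patterns; 20 replicates), and at reduced sizes where only
the mechanism is at stake (50 replicates of n = 400 for the reverse-item
mean-shift property; n = 2000 for loading recovery; 500 null replications
at B = 2000 for permutation uniformity). Loading recovery is judged
against the generating values with a ±0.05 median criterion; the ~0.03
downward bias that 5-category discretization imposes on Pearson-based
loadings is part of that budget.

## Known limitations

* Plain ML only: no robust scaling, no ordinal (polychoric) estimation —
  fit indices on real ordinal data will differ from robust-scaled reports.
* The Fisher z comparison between nested samples inherits the paper-style
  independence approximation.
* The even-odd transform reproduces the conventional range and direction,
  but other software may use a different sign/offset convention; compare
  patterns, not digits.
* The generator's careless archetypes are fully content-blind; partially
  attentive carelessness (the realistic middle ground) is representable
  only through `late_onset`.
* No modification indices, partial-invariance search, or bootstrap CIs for
  fit indices.
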