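---
title: "Evaluating bias in stratified non-linear Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating bias in stratified non-linear Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nlmrbias)
```

## The problem

Non-linear Mendelian randomization (NLMR) estimates how a causal effect
varies across the exposure distribution by splitting a cohort into
exposure-related strata and running instrumental-variable (Wald ratio)
estimation within each stratum. The two stratification schemes in wide use
are:

* the **residual method** — regress the exposure on the genetic instrument
  and stratify on the residuals; valid under the *constant genetic effect*
  assumption (the instrument-exposure effect is the same for everyone);
* the **doubly-ranked method** — rank by the instrument into pre-strata of
  size $S$ (the number of strata), then within each pre-stratum rank by the
  exposure and send the $j$-th lowest to stratum $j$; valid under the
  weaker *rank-preserving* assumption (an individual's exposure rank would
  be unchanged at any counterfactual instrument level).

Both assumptions fail when the genetic effect is *heterogeneous* — for
example, when a variable $u$ modifies the instrument's effect on the
exposure (a $g \times u$ interaction). `nlmrbias` provides a simulation
framework for quantifying the resulting bias, counterfactual diagnostics
for the rank-preserving assumption, and a falsification test that can be
run on real (instrument, exposure) pairs before trusting an NLMR analysis.

## Generating models

The one-confounder design (model A) is
$$x = \beta_g g + b_{ux} u + b_{gux}\, g u + e_x, \qquad
  y = b_{uy} u + e_y,$$
and the two-confounder design (model B) adds an independent $v$ with
effects $b_{vx}$, $b_{vy}$ on exposure and outcome. All latent variables
are mutually independent normal with mean $\mu$ and SD $\sigma$ (defaults
$\mu = 2$, $\sigma = 1$; the instrument may have its own SD
$\sigma_g$). $\beta_g = 0.3$ throughout. Crucially, **the exposure never
causes the outcome**: the true stratum-specific effect is 0 everywhere, so
any systematic deviation of stratum estimates from 0 is bias, and squared
estimates are squared errors.

Independence of $g, u, v, e_x, e_y$ is a modelling choice: the causal
diagrams these designs encode have no arrows among the latent inputs, and
zero cross-correlation is the only consistent reading. Note that the
nonzero mean $\mu = 2$ matters: with $\mu = 0$ and $b_{ux} = 0$ the
interaction term $g u$ is uncorrelated with $u$, and several bias
mechanisms switch off (see "A subtle exception" below).

A separate catalogue of thirteen genotype-exposure models (`M1`-`M13`,
see `model_catalogue()`) is used for rank diagnostics, spanning linear,
interaction, quadratic, and random-coefficient forms. These use mean-0,
SD-1 inputs; `M10` uses $\sigma_g = 0.25$, reading its source's
"SD $= 0.5^2$" literally (the field is exposed in the configuration, so
variance $= 0.25$ is one argument away). For `M11`-`M13` the error and
$u$ are drawn first and the per-individual effect $\alpha$ is then drawn
from its conditional normal — the only order under which those
conditionals are well defined; $\alpha$ is stored on the cohort as a fixed
individual attribute and reused unchanged in counterfactuals.

## Reproducibility and tie handling

One base seed defines a scenario. Replicate $r$ uses the $r$-th entry of
`child_seeds(seed, R)` — a fixed spawning rule (`sample.int` of the 31-bit
range under the base seed) that makes replicates independent and any
single replicate reconstructible in isolation.

All rank-based operations (both stratifiers, the counterfactual rank
metrics) break ties with a deterministic pseudo-random key indexed by
participant `id`, drawn once per call from a fixed tie seed. Keying by
`id` rather than row position makes every assignment equivariant under row
permutation, while avoiding input-order artifacts. Ties are null events
for continuous data; the rule matters only for degenerate inputs. One
numerical guard: in the residual method, residuals smaller than
$10^{-10}\,\mathrm{sd}(x)$ in magnitude are collapsed to an exact tie, so
that exact-fit round-off (order $10^{-16}$) cannot masquerade as ranking
information.

When $S \nmid n$, the final pre-stratum holds $m < S$ members and its
$j$-th lowest-exposure member goes to stratum $\lceil j S / m \rceil$,
preserving monotonicity of stratum in exposure rank while spreading the
remainder.

## Estimation and performance measures

Within each stratum (and in the full sample, reported as stratum 0) the
instrument-exposure and instrument-outcome coefficients come from OLS with
intercept and classical standard errors; the Wald ratio is
$\hat\beta_{gy}/\hat\beta_{gx}$ with first-order delta SE
$\mathrm{se}_{gy}/|\hat\beta_{gx}|$ by default (a second-order option adds
the denominator-uncertainty term; it widens intervals but leaves point
estimates unchanged). Strata with first-stage $F < 10$ are flagged, never
dropped — dropping would distort the bias patterns under study. Covariate
adjustment, when requested, enters both within-stratum regressions;
stratification itself is always unadjusted.

Scenario-level measures follow the usual simulation-study repertoire:

* stratum-wise and pooled **MSE** against the true effect 0 (pooled = mean
  over replicates of the within-replicate across-strata mean; for complete
  matrices this equals the mean of the stratum-wise values, which the test
  suite asserts);
* **Cochran's Q** across stratum estimates (fixed-effect inverse-variance
  pooling — Q's definition) with the **heterogeneity detection rate**: the
  proportion of replicates with $p < 0.05$, strict inequality;
* normal-theory **CI coverage** of 0.

## Rank-preservation diagnostics

For a catalogue model, `counterfactual_exposures()` sets $g$ to fixed
levels ($\mu_g - \sigma_g$, $\mu_g$, $\mu_g + \sigma_g$ by default, using
the configured population moments rather than sample moments) and
recomputes every individual's exposure with their stored $u$, error, and
$\alpha$. `rank_change_metrics()` then reports:

* the proportion of individuals whose rank is identical across all levels;
* the normalized mean rank difference — mean absolute rank change divided
  by $n$ — for every pair of levels, and averaged over pairs. Both the
  all-pairs average and the pairwise map are reported, since a single-pair
  reading is equally defensible.

For any additive model $x = f(g) + u + \varepsilon$ the counterfactual
columns differ by a constant, so ranks are preserved *exactly*; the test
suite asserts this for the linear, reduced-confounder, and quadratic
catalogue models and for randomized nonlinear $f$. Interaction models
violate rank preservation, with severity increasing in the interaction
coefficient ($0.05 < 0.1 < 0.2$ ordering asserted over replicates).
`interaction_metrics()` accompanies these with the fitted $g \times u$
coefficient and the variance share uniquely explained by the product term.

## The falsification test

`falsification_test()` grafts simulated confounding onto a measured
(exposure, polygenic score) pair:
$$x_s = x_{\text{std}} + b_{ux} u, \qquad y_s = b_{uy} u + e_y,$$
with $u, e_y \sim N(2, 1)$ and defaults $b_{ux} = -1$, $b_{uy} = 1$. The
simulated outcome depends only on $(u, e_y)$, both independent of the
score, so the core IV assumptions hold by construction and the true
effect is exactly 0 — the test suite asserts
$\mathrm{cor}(\text{score}, y_s) \approx 0$ in every replicate. Any
systematic stratum-level deviation therefore isolates a failure of the
stratification method's own assumption, typically caused by heterogeneous
genetic effects on the *real* exposure. The exposure is standardized
before the confounder is added (matching how such analyses are prepared);
a constant exposure is passed through unscaled.

The verdict rule is a reporting convention of this package, not an
inherited procedure: "bias suspected" fires when any stratum's absolute
mean estimate exceeds 3 Monte Carlo SEs or the heterogeneity detection
rate exceeds 0.5. Both thresholds are configuration fields and are echoed
in the report.

### The stand-in cohort

`generate_empirical_standin()` supplies a synthetic (score, exposure) pair
shaped like biobank data, for exercising the falsification test without
individual-level human data: 50 biallelic dosages (Binomial(2, $f$),
$f \sim U(0.05, 0.95)$) with uniform weights form the score; a latent
illness-like modifier $m \sim N(0,1)$ both shifts the exposure and scales
the genetic effect through the `heterogeneity` parameter $h$:
$x_{\text{raw}} = (0.3 + h\,m)\,g_{\text{std}} + m + e_x$. These
distributional choices are conventions, not empirical claims. Because the
returned exposure is rescaled to SD 1, coefficients on the analysis scale
are the raw ones divided by $\mathrm{sd}(x_{\text{raw}})$ (stored as the
`"x_scale"` attribute); the parameter-recovery tests compare against that
attenuated truth. What the stand-in does *not* emulate: linkage
disequilibrium, ancestry structure, selection into the cohort, assortative
mating, and real trait distributions — so a clean pass on the stand-in
shows the machinery works, not that any particular real analysis is safe.

### Illness scores

Two generic modifier constructions mirror common practice: a **summary
score** (one point per marker strictly above its 80th / below its 20th
percentile in the harmful direction, plus one per diagnosis flag) and a
**median-rank score** (per-marker ranks in the illness direction, median
across markers, standardized). Quantiles use R's default
linear-interpolation estimator with strict inequality at the threshold —
deterministic and tie-safe; a constant marker therefore contributes no
quantile points, and an all-tied marker set yields a centred zero score
rather than an error. The ranking direction per marker is caller-specified
via the `high_bad` / `low_bad` lists.

## Study sizes used by the checks

The packaged tests and the acceptance script run the one-confounder
scenarios at $n = 20{,}000$ with 50 replicates, the two-confounder
scenarios at $n = 100{,}000$ with 50 replicates (their extreme-stratum
Wald denominators are weaker, so sign calls at 3 Monte Carlo SEs need the
larger cohort), and the rank suite at $n = 10{,}000$ with 20 replicates.
The documented defaults of `run_scenario()` and
`rank_preservation_test()` remain the full study sizes ($n = 100{,}000$ /
$50{,}000$, 100 replicates); all sizes are ordinary arguments.

```{r example, eval = FALSE}
cfg <- scenario_config(n = 100000, seed = 1, n_replicates = 100,
                       b_ux = 0.3, b_gux = -0.1, b_uy = 0.3)
res <- run_scenario(cfg)
res
```

## Known limitations and one cautionary finding

* No scenario includes a non-zero causal effect of exposure on outcome;
  all bias statements are relative to a true effect of 0.
* The Wald SE is first-order by default; second-order SEs widen intervals
  slightly but do not change any qualitative conclusion in the packaged
  scenarios.
* The "each stratum spans the instrument range" property of the
  doubly-ranked method holds on the rank scale (each stratum contains one
  member of every complete pre-stratum, hence spans $\ge 99\%$ of
  instrument ranks at $n = 10^4$, $S = 10$). On the *raw* scale it can
  fall to ~75-85% coverage for a normal instrument, because extreme order
  statistics are widely spaced; with a bounded instrument the raw-scale
  property holds too.
* A subtle exception deserves care. When the exposure follows the
  interaction-only form $x = 0.3 g + 0.1\,g u + \varepsilon$ with all
  means 0, $u$ is *uncorrelated* with $x$ in the population. If the
  outcome is driven by a confounder independent of the exposure machinery,
  stratum estimates are unbiased even though rank preservation is
  violated — the packaged checks assert exactly this. But if the outcome
  is driven by $u$ itself ($y = 0.3 u + e_y$), our simulations show clear
  stratum-level bias (a monotone trend of roughly $-0.14$ to $+0.14$
  across ten strata at $n = 20{,}000$, far beyond Monte Carlo error, in
  both methods) even though the full-sample estimate remains unbiased:
  stratifying on an exposure that contains $g u$ induces within-stratum
  dependence between $g$ and $u$ — a collider — which the
  instrument-outcome regression then picks up. Zero marginal correlation
  between confounder and exposure is therefore *not* sufficient for
  stratum-level validity, only for full-sample validity.
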