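# nlmrbias

Simulation and diagnostic tools for evaluating bias in stratified
("non-linear") Mendelian randomization (NLMR).

## Who this is for

NLMR estimates how a causal effect varies across the exposure
distribution by stratifying a cohort on an exposure-related quantity and
computing an instrumental-variable estimate within each stratum. The two
stratification schemes in common use — the **residual method** (stratify
on residuals of exposure regressed on genotype; assumes a constant
genetic effect) and the **doubly-ranked method** (rank by instrument into
pre-strata, then by exposure within pre-strata; assumes rank
preservation) — both become biased when the genetic effect on the
exposure is heterogeneous, e.g. modified by health status or environment.
`nlmrbias` is for genetic epidemiologists and methodologists who want to

* quantify that bias under controlled simulation designs,
* diagnose violations of the rank-preserving assumption for a catalogue
  of genotype-exposure models, and
* run a **falsification test** on their own (polygenic score, exposure)
  data before trusting stratified MR estimates.

## The models

Cohorts are generated from
\[
x = \beta_g g + b_{ux} u + b_{gux}\, g u + b_{vx} v + e_x,
\qquad
y = b_{uy} u + b_{vy} v + e_y,
\]
with all latent variables independent normal (mean 2, SD 1 by default),
\(\beta_g = 0.3\), and **no causal effect of `x` on `y`** — so the true
stratum-specific Wald ratio is 0 everywhere and any systematic deviation
is bias. Genetic effect heterogeneity is present whenever
\(b_{gux} \neq 0\). Within each stratum the Wald ratio
\(\hat\beta_{gy}/\hat\beta_{gx}\) is computed from the two within-stratum
OLS fits; scenario summaries report stratum means, Monte Carlo SEs,
stratum-wise and pooled MSE, Cochran's-Q heterogeneity detection rate,
and CI coverage. A separate model catalogue (`M1`–`M13`) drives
counterfactual rank-preservation diagnostics: fix `g` at −1 SD / mean /
+1 SD for everyone, recompute exposures holding each individual's other
components fixed, and measure how ranks move.

## Worked example

A scenario with confounding (`b_ux = b_uy = 0.3`) and a gene-by-confounder
interaction (`b_gux = -0.1`):

```r
library(nlmrbias)
cfg <- scenario_config(n = 20000, seed = 1, n_replicates = 50,
                       b_ux = 0.3, b_gux = -0.1, b_uy = 0.3)
res <- run_scenario(cfg)
res
#> <scenario_result>
#> <scenario_config> model A (n = 20000, replicates = 50, strata = 10, seed = 1)
#>   x = 0.3 g +0.3 u -0.1 g*u +0 v + e_x
#>   y = +0.3 u +0 v + e_y
#>   g, u, v, e ~ Normal(mu = 2, sd = 1); sd(g) = 1
#>   residual: pooled MSE 0.1379, heterogeneity rate 0.72
#>     stratum means: 0.513 0.292 0.179 0.105 0.027 -0.032 -0.055 -0.203 -0.349 -0.539
#>   doubly_ranked: pooled MSE 0.1352, heterogeneity rate 0.70
#>     stratum means: 0.464 0.252 0.175 0.118 0.059 -0.095 -0.156 -0.192 -0.282 -0.572
```

Both methods are badly biased — strongly positive estimates in the lowest
strata and negative ones in the highest, despite a true effect of 0 in
every stratum — while the conventional full-sample estimate stays null
(mean 0.0002, 94% CI coverage of zero across replicates):

```r
s <- scenario_summary(res, "doubly_ranked")
round(s$full_sample$mean, 4)   # 2e-04
s$full_sample$coverage         # 0.94
```

The falsification test on a synthetic biobank-like cohort whose genetic
effect is modified by a latent illness-like variable (`heterogeneity =
0.2`) reproduces the same signature on a "real" exposure:

```r
st <- generate_empirical_standin(20000, heterogeneity = 0.2, seed = 2)
fr <- falsification_test(data.frame(id = st$id, prs = st$g, exposure = st$x),
                         semi_empirical_config(n_replicates = 50, seed = 3))
fr
#> <falsification_report> (replicates = 50, strata = 10, b_ux = -1, b_uy = 1)
#>   first-stage F: 900.7
#>   residual: het rate 1.00, bias suspected: YES
#>     stratum means: -0.525 -0.340 -0.271 -0.156 -0.055 0.040 0.103 0.249 0.372 0.393
#>   doubly_ranked: het rate 0.68, bias suspected: YES
#>     stratum means: -0.473 -0.275 -0.129 -0.125 -0.057 0.060 0.076 0.126 0.126 0.178
#>   full-sample coverage of 0: 0.88 (residual)
```

To run it on your own data, supply a delimited table with `id`, `prs`,
`exposure` columns (`read.delim` + `falsification_test`); a boxplot of
per-replicate stratum estimates is available via `plot(fr)`.

Rank-preservation diagnostics for an interaction model
(`x = 0.3g + u + 0.2gu + e`):

```r
rank_preservation_test("M4", n = 10000, n_replicates = 20, seed = 4)
#> <rank_diagnostics> M4 (n = 10000, replicates = 20)
#>   prop. identical ranks : 0.0003
#>   norm. mean rank diff  : 0.0301
#>   GxU interaction beta  : 0.1987 (R2 0.0187)
```

Almost no individual keeps their exposure rank when the instrument is
moved by ±1 SD, so the doubly-ranked method's key assumption fails under
this model; additive models (`M1`, `M2`, `M9`) preserve every rank
exactly.

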