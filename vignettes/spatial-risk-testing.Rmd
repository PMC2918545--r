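---
title: "Testing for spatial variation in disease risk: GAM permutation tests and the Bernoulli scan statistic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for spatial variation in disease risk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gamscan)
```

## The problem

Case-control point data in spatial epidemiology consist of subject
locations $(x_i, y_i)$ and binary outcomes $y_i$. Two questions are asked
of such data: *is* disease risk spatially varying at all (a global test),
and if so, *where* is it elevated or reduced (a local map). This package
implements and compares two families of answers:

* a logistic **generalized additive model (GAM)** with a bivariate LOESS
  smooth of location, tested globally by permutation of the outcomes and
  locally by point-wise permutation tails of the predicted log odds;
* the **circular Bernoulli spatial scan statistic**, which maximises a
  two-rate likelihood ratio over circular zones and calibrates it by
  Monte Carlo relabelling.

Around these sit three synthetic disease-risk generators, closed-form
reference-test power, and a simulation harness for type I error, power
and source-detection sensitivity.

## The smoother

`loess2d()` is a bivariate locally weighted regression: for an evaluation
point $t$, the $q = \lceil s \cdot n \rceil$ nearest subjects (Euclidean
distance; ties at the boundary distance enter together) receive tricube
weights $w_i = (1 - (d_i/d_q)^3)^3$, and a weighted linear model in
$(x, y)$ is solved; the local intercept is the prediction. The *span*
$s$ is the fraction of the data in each neighbourhood. Design choices
the underlying literature leaves open, fixed here:

* **degree 1** (local linear) everywhere — the default of the smoother in
  the software the method family grew up in;
* **raw Euclidean distances**, no predictor normalisation: both axes of
  the generated regions share units, and all statistics are invariant to
  a common rescaling (the local design is centred and scaled by the
  bandwidth $d_q$, so conditioning thresholds are scale-free);
* a **ridge fallback** ($10^{-8}$ relative to the local weight mass) for
  collinear neighbourhoods, and the plain neighbourhood mean if even
  that degenerates;
* duplicate coordinates are counted as points, not unique locations.

Local-linear fits reproduce constants and planes exactly; the test suite
asserts this to machine tolerance, together with a brute-force assembly
of the smoother operator on 25 points whose trace must equal
`smoother_trace()`.

## The GAM and its AIC

`gamloess()` fits $\mathrm{logit}\,P(Y=1) = f(x, y)$ by local scoring:
starting from $\mu_i = (y_i + \bar y)/2$, iterate working response
$z = \eta + (y - \mu)/\mu(1-\mu)$, weights $w = \mu(1 - \mu)$, and
$\eta \leftarrow$ `loess2d`$(z, w)$ until the relative deviance change
falls below $10^{-8}$ (cap 50 iterations; fitted probabilities clipped to
$[10^{-10}, 1 - 10^{-10}]$). The single smooth term absorbs the
intercept, so no backfitting loop is needed.

The effective degrees of freedom are the trace of the linear operator
mapping the working response to fitted values at the converged weights,
and

$$\mathrm{AIC} = D + 2\,\mathrm{edf},$$

with $D$ the binomial deviance. This is the package's **largest
reimplementation assumption**: the original software reported an AIC but
not its df accounting, and no alternative integer-parameter count is
well defined for a model whose only term is the smooth, so no switch is
offered. The choice matters: AIC span selection under a flat-risk null
almost always prefers the largest span here (the edf penalty dominates),
which makes the conditional permutation test *conservative* at its
nominal level in this package's own null calibrations (the acceptance
suite measures roughly 2–4% at the nominal 0.05 cutoff), where the
original report measured an *inflated* 9.5%. The calibrated 0.025
cutoff (below) is retained regardless, and power under the alternatives
agrees with the published estimates.

Span selection minimises AIC over the grid $0.05, 0.10, \ldots, 0.95$
(the published range; the 0.05 step is this package's choice), ties
broken toward the larger, smoother span. Successive grid fits
warm-start from the previous span's probabilities — a numerical
shortcut only, since the fixed point is identified by the convergence
tolerance.

## The four permutation tests

All four compare the difference in deviance
$\Delta D = D_{\mathrm{null}} - D_{\mathrm{smooth}}$ against refits on
datasets with outcomes randomly reassigned to the fixed locations, with
the rank-based p-value $p = (1 + \#\{\Delta D_b \ge \Delta D\})/(B+1)$
(ties counted as exceedances):

| test | span for observed data | span for permutations | cutoff |
|------|------------------------|----------------------|--------|
| CPT  | AIC-optimal            | held at the observed optimum | 0.025 |
| FSPT | fixed a priori         | the same fixed span  | 0.05 |
| FMSPT-$k$ | $k$ fixed spans (0.1/0.5/0.9 or 0.1/0.3/0.5/0.7/0.9) | same, shared permutation stream | $0.05/k$ |
| UPT  | AIC-optimal            | re-optimised per permutation | 0.05 |

The CPT's 0.025 cutoff is the published calibration of its
selection-induced miscalibration at the nominal level. The FMSPT shares
one permutation stream across its spans (one relabelling, $k$ refits),
matching the single-permutation-set reading of the method description
and saving refits. Permutation refits run in lockstep as columns of a
single batched smoother pass; the batched path is bit-identical to
sequential refitting and is what makes desk-scale replication feasible.

Point-wise maps: with probe points supplied, every permutation's
predicted log odds at the probes are stored, and a probe is flagged
**hot** (**cold**) when its observed prediction has rank-based tail
p-value at most 0.025 in the upper (lower) tail. Probe sets are the
caller's choice; the harness uses subject locations (central-cluster
scenario), the region centre (radial scenario) and 101 equally spaced
points on the source line (line scenario). At least 39 permutations are
required to resolve a 2.5% tail; the harness presets use 199 because
$(B+1) \times 0.025$ is then an integer and the tail is attainable
exactly — with 99 permutations the effective tail is 2%, which
depresses sensitivity estimates noticeably.

## The scan statistic

For every subject as centre, the nested sets of its $1 \ldots
\lfloor N/2 \rfloor$ nearest subjects form the candidate zones (tied
distances enter together, so sizes may skip; "continuous radii" collapse
to this finite family). Each zone's Bernoulli log-likelihood ratio
compares case rates inside and outside, in both directions by default —
the package scans high- *and* low-rate zones because the study evaluates
odds ratios below 1, and the OR = 0.5 scenarios discriminate the
settings: with both directions the package reproduces the published
OR = 0.5 power and the published radius distribution of significant
clusters, while high-only scanning does not. The most likely cluster is
the LLR argmax (ties: smaller zone, then smaller centre index); its
radius is the distance to its farthest member, a diagnostic quantity in
the package's own coordinate units. The Monte Carlo p-value ranks the
observed maximum against label-permutation replicates; replicates are
evaluated by case-count thresholds per zone size derived exactly from
the observed maximum, with early exit — decisions are identical to full
evaluation, which the suite verifies against an independent
re-implementation sharing the RNG stream, and against exhaustive zone
enumeration on small configurations.

## Synthetic scenarios

The generators place $n$ subjects uniformly in the study region and draw
outcomes from scenario log odds; `odds_ratio = 1` is the exact null.

1. **Central constant-risk cluster** in a disk: the cluster disk covers
   15% of the region area, so on the package's scale (region radius
   $\sqrt{0.15} \approx 0.387$, cluster radius 0.15) about 150 of 1000
   subjects fall inside — binomially around 150, not fixed. Log odds:
   $\mathrm{logit}(p) + \log(\mathrm{OR})\,\mathbf{1}[\text{inside}]$.
2. **Radial point source**: $\mathrm{logit}(p) + \log(\mathrm{OR})(1 -
   r/R)$ on the same disk; the odds ratio compares the centre to the
   edge.
3. **Vertical line source**: unit square, $\mathrm{logit}(p) +
   \log(\mathrm{OR})(1 - |x - 0.5|/0.5)$; no vertical risk gradient.

The replication defaults ($n = 1000$ subjects, baseline probabilities
0.05/0.20, the odds-ratio grids, 15% cluster area) are the published
study conditions. Every statistic downstream is invariant to rescaling
the regions, so the absolute coordinates are a convention; reported
cluster radii inherit it and are not comparable across conventions
(the published radius table is consistent with a unit region radius).

What the generators deliberately do *not* emulate: non-uniform
population density, covariates other than location, aggregated
(areal) outcomes, multiple or irregular sources. Passing tests
demonstrate calibration and power under these idealised conditions
only.

## Reference tests and theoretical power

The central-cluster scenario reduces, marginally over location, to a
two-group comparison: `chisq_power_case1()` gives the noncentral
chi-square power of the Pearson test with expected group sizes 150/850,
and reproduces the published grid to ±0.001. The two gradient scenarios
admit a simple logistic regression on the exposure score $u \in [0, 1]$
(`exposure_score()`; $u$ has density $2(1-u)$ under the disk, uniform
under the square). `logistic_power()` approximates its two-sided Wald
power through the expected Fisher information (adaptive quadrature,
tolerance $10^{-10}$); the exact small-sample derivation of the original
study is not in print, and the Wald approximation is documented as
accurate to about ±0.05 against the package's own simulation
cross-check `empirical_reference_power()`, with the largest gaps at low
prevalence. Only simulation agreement is asserted, not the published
closed-form column.

## Replication sizes and numerical choices

The full published design (1000 datasets × 999 permutations per
scenario) is hours-per-scenario on one CPU and is available through
`study_config()`. The package's own test suite and acceptance runs use
reduced replication, chosen once: 100–400 datasets at 99 Monte Carlo
replicates for scan quantities; 24–40 datasets at 199 permutations for
GAM-test quantities; 200 null datasets of $n = 150$ for p-value
uniformity; all rejection-rate comparisons carry three combined binomial
standard errors. Other fixed numerics: local-scoring tolerance
$10^{-8}$ and cap 50; probability clipping $10^{-10}$; ridge $10^{-8}$;
rank-based p-values with the +1 correction throughout; per-dataset seeds
derived as `root_seed + index` so any dataset is reproducible in
isolation.

## Known limitations

* The AIC df accounting (above) is an assumption; the conditional
  test's null calibration is sensitive to it, its power much less so.
* Sensitivity definitions are conditional on global rejection and are
  undefined under the null; estimates at small replication carry the
  selection effect of conditioning on few rejections.
* The scan reports the most likely cluster only — no secondary
  clusters, no elliptical or flexibly shaped zones, no covariate
  adjustment.
* Radius diagnostics are convention-bound (see above).

## A worked run

```{r example, eval = FALSE}
d <- generate_dataset(scenario_config(1, 0.2, 3.0, 1000, seed = 7))
fit <- gamloess(d)            # AIC-selected span
summary(fit)

ct <- cpt(d, n_perm = 199, probes = d$coords, seed = 7)
ct                            # global test + hot/cold flags
case1_sensitivity(ct, d, d$region, "high")

sc <- scan_test(d, n_mc = 999, seed = 7)
sc                            # most likely cluster + Monte Carlo p
```
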