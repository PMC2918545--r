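# gamscan

Hypothesis tests for spatial variation in disease risk from case-control
point data: logistic **GAMs with a bivariate LOESS smooth** of location,
tested globally by four permutation schemes and locally by point-wise
permutation tails, alongside the **circular Bernoulli spatial scan
statistic** with Monte Carlo inference — plus the synthetic disease-risk
scenarios, reference-test power theory and the simulation harness needed
to study the type I error, power and source-detection sensitivity of all
of them.

The package is aimed at spatial epidemiologists and biostatisticians who
work with subject-level locations $(x_i, y_i)$ and binary outcomes
$y_i$, and want regression-based smoothing maps and scan-type cluster
detection under one roof, with their operating characteristics
measurable by simulation.

## The statistics

**GAM**: $\mathrm{logit}\,P(Y_i = 1) = f(x_i, y_i)$, with $f$ a
bivariate LOESS smooth (tricube weights over the $q = \lceil s n \rceil$
nearest subjects, local-linear fits), estimated by local scoring. The
global test statistic is the difference in deviance
$\Delta D = D_0 - D_f$ between the intercept-only and smoothed model,
referred to a permutation distribution obtained by relabelling outcomes
over fixed locations:

* **CPT** — span chosen by minimum AIC ($D + 2\,\mathrm{edf}$) on the
  observed data, held fixed for permutations; cutoff 0.025;
* **FSPT** — span fixed a priori; cutoff 0.05;
* **FMSPT-3/5** — fixed spans 0.1/0.5/0.9 (or 0.1/0.3/0.5/0.7/0.9), one
  shared permutation stream, Bonferroni-style cutoff $0.05/k$;
* **UPT** — span re-optimised for every permutation; cutoff 0.05.

A probe location is a **hotspot** (**coldspot**) when its predicted log
odds falls in the upper (lower) 2.5% of its point-wise permutation
distribution.

**Scan**: for every subject as centre, nested circular zones up to half
the study population; each zone's Bernoulli log-likelihood ratio
contrasts case rates inside vs outside (high- and low-rate zones by
default); the maximising zone is the most likely cluster and its p-value
comes from label-permutation replicates.

## A worked example

```r
library(gamscan)

# a central circular cluster covering 15% of a disk-shaped study region,
# baseline disease probability 0.2 outside, odds ratio 3 inside
d <- generate_dataset(scenario_config(1, 0.2, 3.0, 1000, seed = 5))
d
#> Point dataset: 1000 subjects, 244 cases (24.4%), disk region

fit <- gamloess(d)      # AIC-selected span
fit
#> Logistic GAM with bivariate LOESS smooth of location
#>   span 0.20, n = 1000, cases = 244
#>   deviance 1064.776 (null 1111.294, difference 46.518)
#>   edf 17.88, AIC 1100.542

ct <- cpt(d, n_perm = 99, probes = d$coords, seed = 2)
ct
#> CPT: 99 permutations (99 completed), cutoff 0.025
#>   span 0.20: difference in deviance 46.518, p = 0.01
#>   global null REJECTED
#>   probe points: 1000, flagged hot 97, cold 28 (union over spans)

sc <- scan_test(d, n_mc = 99, seed = 3)
sc
#> Bernoulli spatial scan (high+low), 99 Monte Carlo replicates
#> Most likely cluster: high-rate zone of 140 subjects (67 cases)
#>   centred at subject 247, radius 0.1504, llr 21.5476
#>   p = 0.01: null REJECTED at alpha 0.05
```

Both tests reject the flat-risk null at their cutoffs (the permutation
p-values bottom out at $1/(B+1) = 0.01$ here). The scan recovers a
high-rate zone whose radius (0.150) essentially equals the true cluster
radius of the generator (0.15 in the package's coordinate convention),
and the CPT's point-wise map flags about 10% of subject locations as
elevated risk. Source-recovery can then be quantified:

```r
case1_sensitivity(ct, d, d$region, "high")   # 0.608: fraction of the
case1_sensitivity(sc, d, d$region, "high")   # 0.944: true cluster found
```

Power/size studies over the full scenario grid run through
`study_config()` + `run_power_study()`, and `chisq_power_case1()` /
`logistic_power()` give the matching non-spatial reference-test power
(e.g. `chisq_power_case1(0.05, 2)$power` is 0.598).

A thin command-line interface wraps the same functions:

```sh
exec/gamscan simulate --case 1 --p0 0.2 --or 3 --n 1000 --seed 7 --out d.csv
exec/gamscan gam-test --in d.csv --case 1 --method cpt --perms 999 --out r.json
exec/gamscan scan     --in d.csv --case 1 --mc 999 --out s.json
exec/gamscan theory   --case 1 --p0 0.2
```

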