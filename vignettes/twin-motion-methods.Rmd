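---
title: "Methods: head-motion phenotypes and the ACE twin model"
author: "twinmotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: head-motion phenotypes and the ACE twin model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twinmotion)
```

## The problem

Head motion is the main determinant of MRI data quality in young children,
and twin designs make it possible to ask how much of the variation in
motion — and in the blunter outcomes *scan quantity* (how many protocol
runs a child completes) and *scan quality* (how many completed runs survive
quality control) — is genetic rather than environmental. That question
matters for developmental neuroimaging because a heritable motion phenotype
can confound case-control and individual-difference analyses.

`twinmotion` implements the full chain: per-run motion metrics from
rigid-body realignment parameters, run- and subject-level quality-control
decisions, twin correlation statistics, and a from-scratch
maximum-likelihood ACE variance decomposition. A synthetic cohort generator
with a heritable motion propensity makes every stage testable end to end.

## Motion metrics

A run's motion is summarized from its 6-parameter rigid-body series
(3 rotations in radians, 3 translations in mm, one row per volume; the
plain-text `.par` convention, rotations first — a `par_order` switch
handles the translation-first dialect).

**Framewise displacement (FD).** For consecutive volumes,

$$\mathrm{FD}_t = \sum_{k}|\Delta d_{t,k}| + r \sum_{k}|\Delta \theta_{t,k}|,$$

with translations $d$ in mm, rotations $\theta$ in radians and a head
radius $r = 50$ mm (configurable) converting rotations to arc length. The
series has length $N-1$ — no displacement is defined for the first volume
— and a run's mean FD is the mean of those $N-1$ values. Volumes with FD
strictly above 0.3 mm (stringent) or 0.5 mm (lenient) are flagged as
outliers; the flagged *fraction* is computed over the $N-1$ FD frames, not
the $N$ volumes (a documented choice — the two denominators differ by less
than a percentage point on 140-volume runs).

**Absolute displacement (AD).** Per axis, the distance of each volume's
translation from a reference volume, by default the middle volume
($\lfloor N/2\rfloor$, 0-based). Only translations enter AD: per-axis
displacement in mm is how the field tabulates it, and folding rotations
into a per-axis quantity would require choosing a projection; rotations
contribute to FD only. This is a deliberate simplification. Both FD and AD
are invariant to a global constant shift of the parameters and scale
linearly when all parameters are scaled — properties the test suite checks
on randomized traces.

Subject-level phenotypes are unweighted means of the per-run mean FD and
mean AD over the *available* fMRI runs (task and resting state); absent
runs are excluded, never imputed as zero. Cross-run consistency is
quantified with Cronbach's alpha over listwise-complete subjects.

## Quality control

All thresholds are strict inequalities, exactly as printed in quality
protocols:

* task-fMRI runs: included iff maximum per-axis displacement < 3 mm
  (one voxel);
* resting-state runs: included iff strictly fewer than 20% of FD frames
  are flagged (at 0.3 or 0.5 mm, the stringent/lenient variants), or
  optionally by the 3 mm task rule;
* rated scans (T1, DTI): `Excellent`/`Good` under stringent control,
  plus `Doubtful` under lenient; `Failed` never.

**Quantity vs quality denominators.** Quantity counts all 9 protocol runs
(3 SNAT + 2 PCG task runs, T1, 2 DTI, resting state). Quality counts 8
units: the two DTI runs form a single rated unit, since diffusion data are
rated as one judgment. The DTI unit counts as completed only when both DTI
runs were completed. Both denominators live in the protocol object and are
configurable, because 9-run quantity and 8-unit quality ranges coexist in
practice without a canonical reconciliation. Children who never started
have quality fraction `NA`, not zero, and are excluded from quality
statistics.

Subjects are stratified by session-mean motion into nested strata:
*minimal* (mean FD < 0.3 mm and mean AD < 1 mm), else *moderate*
(mean FD < 1 mm and mean AD < 3 mm), else *excessive*. Time-window
inclusion asks whether every quality unit inside the first 30 minutes
(first four task runs), 45 minutes (all five task runs + T1) or 60 minutes
(all 8 units) passed.

## Twin statistics

Within-twin Pearson correlations are computed per zygosity over complete
pairs ordered by birth order (no double entry; the estimate then depends on
ordering only through sampling noise). Two correlations are compared with
the Fisher r-to-z two-sample statistic

$$Z = \frac{\operatorname{atanh} r_1 - \operatorname{atanh} r_2}
{\sqrt{1/(n_1-3) + 1/(n_2-3)}}.$$

Families of distress-outcome correlations are Bonferroni-controlled at a
family-wise level of 0.05 (six tests by default, adjusted level
$\approx$ 0.0083). Distress change over the session is tested with a
one-way within-subject ANOVA, df $(k-1, (k-1)(n-1))$, with
Bonferroni-corrected paired follow-ups; degenerate inputs are handled
explicitly (identical timepoints give $F = 0$; a nonzero effect with zero
error variance raises an error instead of an unbounded $F$).

## The ACE model

Phenotypic variance is decomposed into additive genetic ($a^2$), shared
environmental ($c^2$) and unique environmental/error ($e^2$) components.
Each twin pair is bivariate normal with common mean $\mu$, common variance
$\sigma^2 = a^2+c^2+e^2$ and covariance $\varphi a^2 + c^2$, where the
genetic correlation $\varphi$ is 1 for MZ and 0.5 for DZ pairs and the
shared-environment correlation is 1 for both. A single grand mean and a
common total variance across zygosity groups and twin order is the
homogeneity assumption of the standard model; group-specific means are out
of scope.

**Estimation.** The likelihood is parameterized through unconstrained path
coefficients $(a, c, e)$ whose squares are the variances, which enforces
non-negativity without constrained optimization; the sign ambiguity is
resolved by reporting the squared, sum-normalized shares. Optimization is
a deterministic multi-start BFGS (relative tolerance $10^{-10}$,
effectively $10^{-8}$ on the objective): a Falconer-formula start
($A = 2(r_{MZ}-r_{DZ})$, $C = 2r_{DZ}-r_{MZ}$, $E = 1-r_{MZ}$, clipped and
renormalized, with the $e$ start floored at 0.05 to stay off the singular
$e = 0$ boundary) plus four fixed simplex-corner starts. Data are
standardized internally, so the reported shares are exactly invariant to
shifting or positively rescaling the phenotype. Non-convergence is
reported, never silently ignored. $e = 0$ makes the pair covariance
singular and is rejected inside the objective.

**Confidence intervals** are profile-likelihood: for each share, the values
whose likelihood-ratio statistic stays below $\chi^2_1(0.95) = 3.841$, with
all other parameters re-optimized at every fixed value. Internally the
profiling is cheap because, for fixed within-pair correlations, the ML
solutions for $\mu$ and the total variance are closed-form in the
sufficient statistics; only the split of the remaining variance needs a
1-D numeric search. Endpoints are clipped to $[0,1]$, so a component
estimated at the boundary reports a lower bound of exactly 0 — the typical
`0.00–…` intervals of variance-component tables. If an endpoint search
fails to bracket, the widest bound is returned with a warning.

**Verification.** An exhaustive grid search over the $(a^2, c^2)$ simplex
(default resolution 0.005) with $\mu$ and the variance profiled out
analytically serves as a slow-but-sure reference maximizer
(`ace_grid_search()`); it is algebraically independent of the optimizer
path. Note the grid can only undershoot the true maximum: near
high-curvature optima (e.g. $e^2$ near 0) the fitted log-likelihood
legitimately exceeds the 0.005-grid maximum by more than $10^{-3}$.

**Known statistical behavior.** ML variance shares are boundary-truncated:
with a true $c^2$ of 0, the estimated $c^2$ is non-negative by
construction, so its mean over replicates is positive and the paired
$a^2$ mean is pulled down. At 129 MZ/108 DZ pairs this bias is roughly
0.02–0.08 on $a^2/c^2$ (the acceptance script recomputes these recovery
means), and the sampling SD of $\hat a^2$ is about 0.11. These are
properties of the estimator every standard twin package shares, not of
this implementation — the grid oracle confirms the optimizer finds the
true ML solution, and estimates are consistent as the number of pairs
grows. Profile-CI coverage sits near 95% for interior truths and
97–98.5% for boundary truths (one-sided coverage). Submodel selection
(AE/CE/E) is deliberately out of scope.

## The synthetic cohort generator

The generator emulates the study design the analysis assumes: 256 same-sex
pairs aged 7–9 (55% MZ, rounded half up, so 141 MZ pairs), a fixed 9-run
session (SNAT runs of 148/142/141 volumes, two PCG runs of 136, T1, two
DTI, a 142-volume resting-state run; TR 2.2 s), three-timepoint distress
ratings by child/researcher/parent (parents absent after the scan), and
per-run attrition that jumps after the T1 position.

**Motion.** A latent motion propensity is ACE-structured on the log scale
(default shares 0.65/0/0.35) and acts multiplicatively:
$s = \exp(\sigma_{\log} z)$ scales a per-run process of smooth sinusoidal
drift, AR(1) jitter and sparse spikes, times a within-session multiplier
$1 + 0.05(\text{position}-1)$, so later runs carry stochastically more
motion. Everything is linear in $s$: zero propensity gives all-zero
traces, and doubling the scale doubles every metric.

The log-scale propensity makes motion non-negative and right-skewed, but
it also attenuates heritability on the observed scale: for a lognormal,
the observed correlation is $(e^{\rho\sigma^2}-1)/(e^{\sigma^2}-1)$, which
compresses the MZ–DZ contrast. We chose $\sigma_{\log} = 0.5$ and a drift
amplitude with modest run-to-run variability (uniform within ±25% of its
scale) so that the session-mean phenotype retains about 95% of the latent
twin correlation — still clearly skewed, with occasional >1 mm movers,
while keeping the observed-scale decomposition interpretable. Heavier
tails (e.g. $\sigma_{\log} = 0.8$) are realistic for raw paediatric motion
but push raw-scale correlation estimates into an outlier-dominated regime.

**Distress and attrition.** Tension and excitement are ACE-structured
latents (default 0.10/0.35/0.55 — distress is mostly environmental),
negatively correlated (−0.35). Child means fall for tension
(3.84 → 3.28 → 2.62) and rise for excitement (4.72 → 5.10 → 4.95) across
the three timepoints, on a bounded 1–6 scale (the scale range is
configurable; bounds and means are consistent with smiley-scale ratings).
Researchers and parents load on the same latent (0.9 / 0.45) with a small
positive tension bias — adults rate children as more tense than the
children themselves. Completion is sequential: a 4.7% never-start
probability, a small per-run dropout hazard through T1 (0.004) that jumps
afterwards (0.034), scaled by $\exp(0.5\,\tilde t)$ in the child's
standardized tension. Structural T1/DTI ratings come from an ordinal cut
of the motion propensity plus noise, calibrated to marginals of
31/43/16/10% (T1) and 86/8/4/2% (DTI).

All randomness flows from one root seed through fixed, named substreams
(phenotypes, subjects, distress, traces), so stages are independently
reproducible and `generate_cohort()` is deterministic given
`(config, seed)`.

**What the generator does not emulate:** scanner drift, respiratory and
thermal noise, the exact joint distribution of real motion across runs, or
the real cohort's descriptive statistics. Passing tests therefore show the
pipeline is correct and the estimator behaves as designed under the
assumed data-generating process — not that any particular real dataset
would yield particular estimates.

## Problem sizes and numerical choices

The test and acceptance suites use sizes chosen to balance Monte-Carlo
error against runtime as a design choice: 25 small datasets (≤ 40 pairs)
for the grid-oracle comparison; 200 replicates per generating triple at
129 MZ/108 DZ pairs for parameter recovery and CI coverage; 50 replicate
256-pair cohorts for end-to-end heritability recovery. Profile endpoints
use `uniroot` at tolerance $10^{-5}$ with the remainder-split optimized at
$10^{-7}$; Cronbach's alpha errors on zero total variance; correlation
functions require at least 3 complete pairs; the ACE fit requires 2 pairs
per zygosity group and a non-degenerate phenotype.

## Limitations

* The ACE fit assumes bivariate normality; session-mean motion is
  right-skewed, and the raw-scale decomposition inherits the moment
  structure of the data, not a transformation-invariant quantity.
* Boundary truncation biases small-sample share estimates (above); means
  of replicated estimates should not be read as unbiased recoveries.
* The quality denominator treats DTI as one unit; protocols that rate DTI
  runs separately should override `quality_denominator`.
* No sex-limitation, ascertainment or multivariate twin models.
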