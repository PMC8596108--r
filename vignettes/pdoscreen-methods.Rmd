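---
title: "Methods: organoid pharmaco-phenotyping with pdoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organoid pharmaco-phenotyping with pdoscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdoscreen)
```

`pdoscreen` analyses ex vivo drug-sensitivity screens on patient-derived
organoids (PDOs). This vignette documents the models and procedures the
package implements, the parameters that matter, the design choices that
were genuinely open, and what the synthetic-data generators do and do not
emulate.

## The screening design

A screen exposes each organoid line to each panel drug in a dilution
series — by default 7 points, threefold apart, from a 20 µM top dose
(so the lowest tested concentration is 20e-6 / 3^6 = 27.4 nM) — in
three technical replicate wells, alongside vehicle negative controls
(0.2% DMSO) and a maximally cytotoxic positive control (1 µM
bortezomib). Concentrations are stored in molar units throughout;
display formatting (µM/nM) is cosmetic. Plate data are long, tidy
tables rather than well grids: the analysis never uses plate geometry,
and a well-position column is treated as optional metadata.

## Normalization

Percent viability anchors the negative-control mean at 100% and the
positive-control mean at 0%:

$$v = 100\,\frac{s - \bar{s}_{pos}}{\bar{s}_{neg} - \bar{s}_{pos}}.$$

Whether the original assay normalized against both controls or the
vehicle alone is not decidable from the assay description; two-anchor
normalization is the default because the positive control is on every
plate and guards against additive background, and `anchor = "neg_only"`
switches to vehicle-only normalization. Values below 0% or above 100%
are retained — clipping would bias the curve fit. Normalization is
invariant to rescaling all raw signals, so plate-level gain differences
cancel.

## Dose–response model and IC50

Viability is modelled by the four-parameter logistic

$$v(c) = b + \frac{t - b}{1 + (c/e)^{h}},\qquad h > 0,$$

with upper/lower asymptotes $t \ge b$, Hill slope $h$ and inflection
$e$ (EC50). Fitting minimizes the residual sum of squares over **all
replicate wells** (not per-dose means), preserving the replicate error
structure. The optimizer is deliberately simple and checkable:

1. a coarse grid over $\log_{10} e$ (tested range ± 2 decades, 40
   points) × $h \in \{0.5, 0.75, 1, 1.5, 2, 3, 4\}$, solving the
   asymptotes in closed form at each node (the model is linear in
   $(b, t)$ given the shape);
2. Nelder–Mead refinement of all four parameters (restarted once,
   relative tolerance 1e-12);
3. a Levenberg–Marquardt polish, accepted only if it lowers the RSS.

Asymptotes are constrained to a generous viability box
($[-100, 400]$%): outside it an asymptote is an unidentifiable
extrapolation (e.g. a curve that barely begins to fall at the top
dose), and unconstrained fits can otherwise wander to absurd values
without changing the fitted curve inside the tested range. Hill slopes
are bounded to $[0.05, 20]$. A fit whose dynamic range collapses below
one viability point is flagged degenerate; a refinement that cannot
improve on the grid is flagged but still returns the grid-best
parameters. The refined fit is asserted in the test suite to never do
worse than the brute-force grid oracle.

The **IC50 is the absolute 50%-viability crossing** of the fitted
curve, not the relative-to-asymptote EC50 — drug sensitivity is defined
as the concentration that inhibits half the cells. Censoring handles
non-crossing curves: viability ≥ 50% across the tested range assigns
the top tested dose (`at_max`); ≤ 50% everywhere assigns the lowest
dose (`at_min`). Interior IC50s are clamped to the open tested range.
This makes `extract_ic50` total (no failure mode) and monotone:
uniformly lowering a curve never raises its IC50.

Replicate QC computes the per-concentration coefficient of variation
(sample SD / mean of the normalized replicates) and fails a curve when
the median CV exceeds 20% (configurable). Failed curves are still
fitted and flagged; exclusion is a downstream choice, since a censored
resistant curve with noisy replicates still carries usable information.

## Tertile response calls

Per drug, PDOs are ranked by IC50 ascending and cut at ranks
$\lceil n/3 \rceil$ and $\lceil 2n/3 \rceil$: sensitive, moderate,
resistant. For $n = 75$ distinct values this yields exactly 25/25/25;
for $n = 76$, 26/25/25. Ties share the label of the lower rank block —
the direction is arbitrary but deterministic and documented.

When more than a third of the cohort is censored at a range bound the
tertile quantiles collapse onto the bound, so a **bound rule** applies:
all `at_max` lines are resistant (respectively all `at_min` lines
sensitive) and the uncensored remainder is split into two equal-rank
halves. The original rule says only that the remainder is "subdivided
into two groups"; the equal-halves reading is this package's
interpretation, flagged as such. If **both** censored fractions exceed
the threshold, no assignment is defensible and the classifier raises an
ambiguity error rather than guessing. Tertiles are computed per drug
across the full cohort (consistent with how the screen heatmaps are
drawn); sub-cohort tertiles are not offered.

Treatment-level rollup takes the best label in the regimen
(sensitive > moderate > resistant). A treatment is predicted effective
iff its best call is sensitive; the alternative rule where moderate
also counts is available (`moderate_counts_good`) but not default,
because good outcomes concentrate in the ≥1-sensitive stratum while
the no-sensitive-no-moderate stratum is dominated by progression. The
continuous score $(\#sensitive + 0.5\,\#moderate)/\#called$ is used
only as the AUC ranking variable. Drugs the platform cannot evaluate
(liver-activated prodrugs such as cyclophosphamide or capecitabine,
anti-angiogenics, hormone modulators) simply have no call; a regimen
with no called drug is flagged untestable and excluded with a count.

## Combinations

With a partner fixed at its IC30 (residual viability 0.70), the
predicted-additive curve under Bliss-style independence is the
pointwise product of the gradient drug's mean viability and 0.70. The
excess score is the mean of (predicted − observed) viability over the
shared grid; zero under independence, positive for
stronger-than-additive combinations. No Loewe or Chou–Talalay indices
are computed — the comparison is deliberately the simple additive
expectation.

## The response signature

Pan-sensitive and pan-resistant groups are PDOs called sensitive
(resp. resistant) to **all six** microtubule-targeting drugs. The
differential-expression statistic is a per-gene Welch t on log2(CPM+1)
— a deliberate, documented deviation from count-model packages: it is
self-contained, assumption-light at the ≥3-per-group sample sizes
involved, and preserves the published thresholds (BH FDR ≤ 0.01, fold
change ≥ 2, applied two-sided as $|\log_2 FC| \ge 1$ since the
signature contains both directions).

The correlation filter computes the tie-corrected Spearman ρ of each
DE hit against a per-PDO summary of the six IC50s. The original
description does not say whether ρ is taken per drug or against a
summary; the **median log10 IC50 across the six drugs** is used because
it is robust to a single censored drug, and "correlation higher than
0.3" is read as $|\rho| > 0.3$ **with direction consistency**: a gene
up in sensitive lines must anticorrelate with IC50. Every emitted
signature gene is re-asserted against all three thresholds at output.

Clustering uses average-linkage agglomeration on $1 - r$ (Pearson)
between signature profiles, cut at $k = 2$; the cluster with higher
mean expression of up-in-sensitive genes is the sensitive class. The
classifier is a linear SVM (the standard tool for this task) on
features standardized with **training-data statistics only**; missing
signature genes in external data are imputed at the training mean and
counted. In the full pipeline, when the strict all-six grouping leaves
fewer than three PDOs in a group — common in small cohorts — the DE
grouping falls back to tertiles of the six-drug median log10 IC50, and
the fallback is logged.

## Survival and concordance

Kaplan–Meier estimation and the two-group log-rank test are delegated
to the `survival` package behind the module interface; the test suite
checks both against hand-computed product-limit and
observed-minus-expected oracles. Concordance is evaluated at the
**treatment** level (one regimen = one unit), matching how the
retrospective comparison is framed; patient-level clustering of
repeated regimens is a known limitation. RECIST CR/PR/SD map to good
response and PD to poor; for incurable advanced disease, stable disease
is an acceptable outcome, which is why SD counts as good. Unknown
outcomes are excluded listwise with a reported count.

Confidence intervals are percentile bootstrap over 1000 treatment-level
resamples with endpoints taken as order statistics; the interval is
deterministic for a fixed seed. The AUC is the rank-based (Mann–Whitney)
area using the continuous treatment score — with essentially binary
predictions an AUC needs a ranking variable, and the published AUC's
input is not recoverable, so the score-based definition is documented
rather than matched. The association test is Pearson's chi-square
without continuity correction, as named. Two descriptive utilities
round out the genomic-concordance arithmetic: the preserved fraction of
a parental alteration gene set, and the cosine similarity of
mutational-signature contribution vectors (the similarity metric was
unstated; cosine is the standard choice for non-negative contribution
vectors).

## Synthetic-data generators

The generators define the study conditions the tests run under:

* **Screen** (`simulate_screen`): 76 lines × 49 drugs (19 breast / 30
  other — the 19+30 split is the only arithmetic consistent with the
  panel size), 7-point threefold series from 20 µM, triplicates.
  True curves are 4PL with top ≈ 100%, bottom in [0, 8]%, Hill in
  [0.8, 2.2]; log10 EC50 is uniform over a window extending ~0.5–0.8
  decades beyond the tested range, so `at_max`/`at_min` censoring
  arises naturally. The six microtubule drugs load (0.9 decades/SD) on
  a shared per-PDO latent factor, planting the correlated block and
  the pan-sensitive/pan-resistant tertiles. Noise is multiplicative
  mean-one lognormal at CV 10% — luminescence scales with cell number,
  so noise is proportional; no noise model was published and CV 10% is
  this package's choice, exposed in the configuration.
* **Expression** (`simulate_expression`): negative-binomial counts
  (dispersion 0.15 by default), library sizes spanning exactly 2-fold,
  and signature genes shifted ±effect/2 between the outer latent
  tertiles — giving both the planted fold change and the monotone
  IC50 association.
* **Clinic** (`simulate_clinic`): regimens of 1–3 drugs from one PDO's
  calls; P(good | ≥1 sensitive) = 0.71 and P(PD | no sensitive) = 0.93.
  The moderate-best stratum has no published probability of its own and
  by default inherits the no-sensitive law, which also makes the
  degenerate case (both probabilities 1) yield exactly 100% concordance
  accuracy; `p_good_given_moderate` overrides it.
* **Survival** (`simulate_survival`): exponential event times, hazard
  ratio 3 (non-sensitive vs sensitive-signature), independent
  exponential censoring calibrated so the expected censored fraction is
  20% per group.

What the generators do **not** emulate: plate-edge and position
effects, drug-specific range adjustments made mid-screen, batch effects
or composition bias in RNA-seq, patient-level correlation between
repeated treatments, and informative censoring. Passing tests therefore
demonstrate correctness of the analysis machinery under the assumed
statistical structure, not robustness to those real-data artifacts.

## Numerical choices and problem sizes

All randomness flows from one integer seed; pipeline stages derive
child seeds deterministically, outputs are plain text with fixed
formatting, and a fixed-seed rerun is byte-identical. Degenerate inputs
fail loudly: missing controls, non-positive control contrast, all-zero
libraries, one-class training sets, zero chi-square margins and empty
parental gene sets are errors, not silent NAs.

The test suite exercises the statistical claims at deliberately scaled
sizes chosen to keep the default run around a minute while leaving the
Monte Carlo error well inside the asserted bands: 500 curves for IC50
recovery under CV 10% noise (≥95% within 2-fold of truth), 2000 genes /
10 vs 10 PDOs for signature recovery (sensitivity ≥ 0.9, empirical FDR
≤ 0.05), 3000 simulated treatments for concordance convergence, 200
outer replications × 1000 resamples for bootstrap coverage, 1000
simulations for null calibration of log-rank and chi-square, and a
12-PDO × 10-drug pipeline for the byte-identity check. Generator
defaults stay at the study scale (76 × 49).
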