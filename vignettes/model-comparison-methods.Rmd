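---
title: "Methods: heterogeneity scoring, combination indices and synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heterogeneity scoring, combination indices and synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmshet)
```

This vignette documents the statistical procedures the package implements,
the choices made where the underlying conventions are genuinely open, and
what the synthetic-data generators do and do not emulate.

## Staining-intensity profiles and their scores

The unit of analysis is a per-sample, per-marker fraction vector
$p = (p_0, p_1, p_2, p_3)$ over the four ordinal immunostaining intensities
0/+/++/+++. Fractions are validated as nonnegative and renormalized to sum
to one on entry; cell counts are converted with `intensity_fractions()`,
which refuses all-zero (empty) samples.

Two scores are computed from the consensus profile:

* **H-score** $= 100\sum_i i\,p_i$, the standard semi-quantitative
  pathology score on the 0–300 scale. It is linear in the profile, so a
  mixture of two cell populations scores the mixture of their H-scores.
* **Shannon Diversity Index** $\mathrm{SDI} = -\sum_i p_i \ln p_i$ with the
  convention $0 \ln 0 = 0$, on the natural-log scale, bounded by $[0,\ln 4]$
  for four bins. SDI is permutation-invariant in the bins: it measures how
  mixed the staining is, not which grades are involved.

**Observer consensus.** Scoring protocols with two independent observers
rarely state a reconciliation rule. We use the element-wise mean of the
observers' fraction vectors (renormalized). The mean is unbiased for the
underlying profile when observers read independent fields of the same
section, and it nearly halves the multinomial reading variance.

**Per-sample heterogeneity call.** Published cohort tables count samples as
"heterogeneous" without quantifying the rule. The package calls a sample
heterogeneous when at least two intensity bins each hold at least
`min_minor_fraction` of the cells (default 0.10). Two occupied bins is the
minimal notion of mixed staining; the 10% floor makes the call robust to
single stray cells while catching any visually evident minority population.
The threshold is a tunable parameter of `score_cohort()` and
`call_sample_heterogeneity()` and must lie in (0, 0.5] — above 0.5 no two
bins could both qualify.

**Cohort pooling and the >40% rule.** A marker is cohort-level
heterogeneous when strictly more than 40% of evaluated samples are
heterogeneous. The percentage is computed from pooled counts
($\sum$ heterogeneous / $\sum$ evaluated over subtypes), not as a mean of
per-subtype percentages: pooling weights subtypes by how many samples were
actually evaluable, and it reproduces more rows of the reference panel
exactly. Subtypes with zero evaluated samples are excluded rather than
treated as 0/0. Percentages are rounded half away from zero
(`round_half_away()`), the convention that matches 10 of the 14 published
aggregates.

**The reference panel.** `reference_marker_counts()` ships the per-subtype
heterogeneous/evaluated counts of a published 14-marker breast-cancer
survey (Luminal A/B, HER2+, triple-negative; 6–10 evaluable cases per
cell). `reference_marker_consistency()` recomputes each pooled percentage
and compares it with the percentage printed alongside the counts: ten rows
agree exactly under the pooled-count convention; Rictor, p-mTOR and FASN
match neither pooled counts nor the mean of subtype percentages, and p-S6
pools to 86.49 (rounding to 86, one below its printed 87). These rows are
*flagged* as inconsistent, never forced: the discrepancies live in the
source table, not in the arithmetic.

## Drug response

**Normalization.** `normalize_to_control()` expresses treated readouts as
control %, $100 \cdot \bar{x}_{\mathrm{treated}} / \bar{x}_{\mathrm{control}}$,
per model and assay; the replicate-level percentages supply the SD. The
control normalized against itself is exactly 100 by construction.
`average_across_assays()` then takes the unweighted mean over assays
(metabolic, protein, counting) — unweighted because the different tests are
treated as equally credible views of proliferation.

**Effects and the combination index.** The effect of an arm is fractional
inhibition $E = \max(0,\, 1 - \mathrm{viability}/100)$, clipped at 1.
Clipping at 0 means growth stimulation is "no effect" rather than a
negative effect, which keeps the combination index positive and
interpretable. For a combination with monotherapy effects $E_a, E_b$ and
combined effect $E_{ab} > 0$:

$$\mathrm{CI} = \frac{E_a + E_b}{E_{ab}}$$

with CI < 1 synergistic, CI = 1 additive, CI > 1 no additional effect.
Exact additivity has probability zero on noisy data, so additivity is
declared inside a band $|\mathrm{CI} - 1| \le \tau$ with $\tau = 0.05$ by
default (configurable everywhere it is used). The index is scale-invariant:
multiplying all three effects by a common factor leaves it unchanged.
$E_{ab} = 0$ is an error, not an infinite index.

**Sensitivity classes.** Viability maps to four classes: resistant
($\ge 90$), minimal sensitivity ($[80, 90)$), sensitive ($[60, 80)$),
highly sensitive ($< 60$). The published wording "resistance ~90%; minimal
sensitivity > 80%" overlaps at the boundary; we disambiguate to half-open
bands so the classification is a monotone function of viability.

**Concordance.** `model_concordance()` scores two systems by the fraction
of arms with identical class; `rank_model_concordance()` orders candidate
systems against a reference, breaking agreement ties by the smaller mean
absolute viability difference. Because class calls flip when a true
viability sits near a band boundary under assay noise, concordance
*rankings* are best interpreted on agreement averaged over replicate
experiments, which is how both the test suite and the acceptance script use
them.

## Xenograft volumes

Caliper pairs are converted with the geometric-mean-diameter sphere
formula, $V = \frac{\pi}{6}\left(\frac{2 s + \ell}{3}\right)^3$ in mm³
(diameters in mm). The source rendering of this formula is typographically
garbled; we adopt this standard convention — the shorter diameter counted
twice because subcutaneous tumour depth tracks width — under which equal
diameters reduce exactly to the sphere volume and doubling both diameters
multiplies volume by 8. Swapped caliper pairs are corrected on ingest. The
in vivo treatment effect is the endpoint burden reduction
$E = 1 - \bar{V}_{\mathrm{treated}}/\bar{V}_{\mathrm{control}}$ (clipped to
$[0,1]$), with final mean volume as the default basis and final mean weight
as the alternative; the source reports both endpoints without naming which
fed its combination indices, and volume is chosen because it is observed
longitudinally.

## What the synthetic generators emulate

The generators produce data with exactly the statistical structure the
scoring assumes, so that every estimate the package makes can be checked
against a known truth.

**Cohorts** (`simulate_cohort()`). Each sample is truly heterogeneous with
its marker's prevalence $\theta_m$. Heterogeneous profiles are symmetric
Dirichlet draws (per-bin concentration 1 — uniform on the simplex) and
homogeneous profiles put concentration 10 on a uniformly chosen dominant
bin; both are rejection-conditioned on the per-sample heterogeneity rule
with a separation margin of $0.25\times$ the call threshold (second-largest
fraction $\ge 0.125$ versus $< 0.075$ at the default 0.10). The margin
gives the generator an unambiguous ground truth: profiles sitting exactly
on the call boundary would otherwise be misread from finite cell counts at
a rate of several percent, which would make prevalence unrecoverable at
binomial precision. Observers read samples by multinomial sampling of
`n_cells` = 300 cells (a realistic order for a scored section;
`n_cells = Inf` gives exact reads). Under these defaults, heterogeneous
samples have median SDI ≈ 1.1 and homogeneous samples mean SDI ≈ 0.4,
inside the 0.33–1.28 range reported for experimental-model panels; the
defaults were calibrated once by simulation to sit in that range and were
not revisited. Default marker prevalences are the pooled percentages of
the reference panel; default cohort sizes are 10 samples per subtype.

**Plates** (`simulate_assay_plate()`). Replicate signals are
$v^\*(1+\varepsilon)$, $\varepsilon \sim N(0, \mathrm{CV})$ truncated at
zero — multiplicative Gaussian noise, the typical plate-reader behaviour —
with CV = 0.10 and 6 replicates by default. Combination-arm truth is
constructed from the monotherapy effects and a *true* combination index:
$E_{ab} = (E_a + E_b)/\mathrm{CI}^\*$, truncated to $[0,1]$, so recovery of
$\mathrm{CI}^\*$ by the scoring path is a meaningful self-test. The default
arm layout encodes the qualitative cross-model pattern the package is
designed to detect: 2D sensitive to every arm (70/75/65% for
rapamycin/doxycycline/doxorubicin), spheroids sensitive to rapamycin and
doxorubicin but not doxycycline (70/88/72%), and scaffold and xenograft
resistant to all monotherapies (94/96/95%, clearly inside the resistant
band rather than on its 90% boundary) with strongly synergistic
combinations ($\mathrm{CI}^\* = 0.22$ and $0.20$) that pull viability below
60%. Model-to-assay mapping mirrors practice: three assays for 2D, two for
spheroids and scaffolds, endpoint volume for the xenograft arm.

**Xenografts** (`simulate_xenograft_study()`). Control volumes grow
exponentially from 50 mm³ (palpable) by 8-fold over 21 days; a treated
group's rate is reduced so that its endpoint equals the control endpoint
times the group multiplier exactly, making the noiseless in vivo effect
equal to $1 - \text{multiplier}$ by construction. Diameters are
back-computed from the sphere volume and jittered with 0.3 mm Gaussian
noise per caliper reading; thrice-weekly measurement days over 21 days,
6 animals per group; endpoint weight is volume × 1 mg/mm³.

All generators are deterministic given their `seed` argument (one stream
per generator call).

**What they do not emulate.** No spatial structure within sections (SDI per
whole sample only), no inter-observer bias (observers differ only by
multinomial reading noise), no dose–response (single concentrations, as in
the comparison the package supports), no plate-position or batch effects,
no pharmacokinetics and no tumour-growth-curve shapes beyond exponential.
Passing recovery tests on these generators therefore shows the *scoring
arithmetic* is correct and well-calibrated under the stated noise model; it
does not certify behaviour on real data with observer bias, spatial
heterogeneity or heavier-tailed assay noise.

## Numerical and statistical choices

* Percent rounding is half-away-from-zero; the cohort flag uses a strict
  `> 40` comparison, so a marker at exactly 40% is not heterogeneous.
* Fraction vectors are renormalized on entry with a hard error for empty
  or negative input; entropy uses only the positive entries, which is the
  $0\ln 0 = 0$ convention at machine precision (the implementation agrees
  with explicit term-by-term summation to $< 10^{-12}$; the test suite
  checks 1,000 random profiles).
* The additivity band $\tau = 0.05$ is a deliberate compromise: at CV 10%
  with 6 replicates the recovered CI has spread comparable to the band, so
  "additive" is only claimed near-exactly; with large monotherapy effects
  non-additive classes are called correctly in ≥ 90% of plates (checked by
  simulation at true CI 0.7 and 1.4).
* Prevalence recovery is judged against the *exact binomial* 95% band for
  the realized cohort size. A subtlety worth recording: the >40% flag is a
  deterministic function of the heterogeneous-sample count
  $K \sim \mathrm{Bin}(n, \theta)$, so even perfect per-sample calls cannot
  make it always correct near the cutoff — at $n = 37$, $\theta = 0.5$ the
  flag is wrong whenever $K \le 14$, probability 0.094. The test suite
  therefore requires the observed flag-accuracy to reach this
  exact-binomial cap minus three Monte-Carlo standard errors, rather than
  an unattainable 100%.
* Degenerate ANOVA groups (zero residual variance) in
  `significance_annotations()` are reported as "degenerate" with a
  mean-difference flag instead of a p-value, and arms are compared to
  control with Tukey-adjusted p-values within each model × assay family
  (no cross-model correction).

## Problem sizes

The test suite and acceptance script use: 1,000 random profiles for the
entropy oracle; 500 simulated plates per true CI (CV 0.10, 6 replicates);
300 replications of 37-sample cohorts per prevalence in {0.2, 0.5, 0.9};
20 replicate experiments for the concordance ranking; 10 samples per model
for the SDI panel; and 6 animals per group for the xenograft recovery.
These sizes put Monte-Carlo error well below each quantity's acceptance
margin while keeping a full run to a few minutes on one CPU.

## Known limitations

* The per-sample heterogeneity rule is a reasonable formalization, not the
  (unpublished) one behind the reference counts; cohort flags on real
  cohorts may shift near the 10% bin threshold.
* Concordance is computed on a handful of arms, so its values are coarse
  (multiples of 1/6 with the default layout); rankings, not magnitudes,
  are the meaningful output, and they should be averaged over replicate
  experiments.
* The in vivo effect uses endpoint means only; it ignores longitudinal
  information and animal-level pairing.
* SDI treats the four intensity grades as unordered categories; two
  samples with the same mixedness but different grade composition are
  indistinguishable to it (the H-score carries the ordering).
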