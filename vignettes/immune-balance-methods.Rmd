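---
title: "Quantifying immune dysregulation from subset frequencies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying immune dysregulation from subset frequencies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ImmuneBalance)
```

## The problem

Inborn errors of immunity (IEI) span a continuum from "pure" infection
susceptibility to primary immune regulatory disorders (PIRD), in which
autoimmunity, chronic inflammation, lymphoproliferation and malignancy
dominate the clinical picture. At the cellular level this state shows up as
an imbalance between regulatory populations (CD4+CD25hiCD127loFOXP3+ Tregs,
transitional and memory regulatory B cells) and inflammatory populations
(BCL6+ and ICOS+BCL6+ follicular-helper-like cells, activated CD8+CD25+
T cells). `ImmuneBalance` works from post-gated flow-cytometry tables —
samples by subsets, each value a percent-of-parent frequency — and asks: can
the regulatory/inflammatory imbalance be condensed into a single
quantitative score, related to binary clinical-domain data, and validated
with honest internal-validation machinery?

## The Immune Dysregulation Score

The core statistic is a balance in the compositional-data sense: the
log-ratio of geometric means of the inflammatory over the regulatory panel,

$$\mathrm{IDS} = \log\frac{\mathrm{GM}(x_{\mathrm{BCL6^+}},
x_{\mathrm{ICOS^+BCL6^+}}, x_{\mathrm{CD8^+CD25^+}})}
{\mathrm{GM}(x_{\mathrm{Treg}}, x_{\mathrm{trans.\,Breg}},
x_{\mathrm{mem.\,Breg}})}.$$

Properties that the test suite verifies to machine precision: swapping the
two panel lists negates the IDS; multiplying all inflammatory frequencies by
$c$ adds exactly $\log c$; the order of subsets within a list is
irrelevant. Design choices:

* **Log base.** Natural log. The base is recorded in the score metadata
  sidecar so results are convertible.
* **Zeros.** Real percent-of-parent tables contain zeros; a pseudocount
  (default 0.01 percentage points) is added to every frequency before the
  log. The default is small enough that it does not move non-zero values at
  typical gating resolutions.
* **ΔIDS** is the IDS minus the control-group mean IDS, so controls centre
  at zero exactly. **Pro_mean / Anti_mean** are arithmetic means of
  control-standardized (z-scored against control mean and SD) frequencies of
  the respective panel triplets — the three subsets on each side live on
  different scales, so standardization precedes averaging. Cohorts whose
  control group is constant in a panel subset are rejected rather than
  silently producing infinite z-scores.

The clinical counterpart (CDS) is the sum of binary manifestation domains.
Two presets exist: the four-manifestation set (autoimmunity, chronic
inflammation, lymphoproliferation, malignancy; range 0–4, the default) and a
six-domain set (autoimmune/inflammatory, malignancy, lymphadenopathy,
recurrent infections, dysgammaglobulinemia, hepatosplenomegaly). Patients
missing any domain are excluded from clinical scoring rather than imputed;
the clinical z-score is the CDS standardized over scored patients only
(controls carry no clinical table) and is undefined when fewer than two
distinct CDS values exist.

## The synthetic cohort generator

No patient-level data ship with the package; the generator produces cohorts
with the statistical structure the analysis assumes, so every stage is
testable. Frequencies are simulated on the logit scale — Gaussian draws
around per-subset baselines, back-transformed with
$100\,\mathrm{plogis}(z)$ — which respects the (0, 100) bounds and makes
planted correlations approximately survive the transform. Defaults are the
study conditions the package targets:

* 39 patients and 17 controls;
* twelve subsets (the six panel members plus six bystanders that give the
  correlation and metaclustering stages realistic width) with baseline
  percent-of-parent means between 1.5% and 35%;
* signed patient effects: Treg, transitional Breg, memory Breg and memory T
  cells shifted down; BCL6+, ICOS+BCL6+, CD8+CD25+, IL-17A+, plasmablasts
  and CD8+HLA-DR+ shifted up. Magnitudes (0.6–1.2 logit units at full
  coupling) are free parameters chosen for testability: group tests and ROC
  analyses land in realistic, non-saturated ranges at the default cohort
  size.
* a latent severity per patient, Beta(2, 2) on [0, 1], that drives both the
  cellular shifts and the Bernoulli probabilities of the binary clinical
  domains (each domain probability is `intercept + slope * severity` with
  increasing slopes).

**Severity coupling.** One latent axis must couple cells and clinic, and the
empirical structure this package targets has the clinically most burdened
patients *not* showing the largest cellular imbalance: the IDS correlates
negatively with the clinical z-score across patients even though patients as
a group sit above controls. The generator therefore scales each patient's
cellular shift by `1 - severity` by default while clinical domain
probabilities increase with severity. Both couplings are monotone, so the
directional group effects and the severity/clinical-burden coupling are
preserved; `cellularCoupling = "direct"` switches to shifts that grow with
severity for users who want the opposite regime.

What the generator does **not** emulate: event-level FCS data, spillover,
batch effects, age-structured reference ranges, or heavy-tailed measurement
error. Passing tests therefore demonstrate the correctness of the
machinery, not the clinical performance of the score on real cohorts.

```{r generator}
cfg <- simulationConfig(seed = 1)
coh <- generateCohort(cfg)
coh
```

## Group tests, correlation networks, embedding

Per-subset patient-versus-control comparisons use two-sided Mann–Whitney
tests (exact when both groups have at most eight samples and the data are
tie-free, normal approximation with tie correction otherwise) with
Benjamini–Hochberg control over the subsets tested in one call. Subsets that
are constant across the cohort have no defined statistic: they are flagged
and excluded from the FDR family rather than assigned a fake p-value.

Correlation matrices default to Spearman — percentages are bounded and
often skewed, and rank correlations are invariant under the monotone
logit transform the generator uses. Pearson is reserved for the
IDS–clinical-z association. The delta network connects subset pairs whose
correlation changes by at least 0.4 (configurable; no canonical threshold
exists) between groups; undefined correlations never form edges, and
`strongerIn` records the group with the larger signed correlation, so a
positive association that collapses or flips in patients is reported as
stronger in controls. The package deliberately attaches no significance
test to individual Δr edges.

The 2D embedding is an exact (dense) t-SNE written for cohort-sized inputs
(tens to a few hundred samples): perplexity-calibrated Gaussian affinities,
Student-t output kernel, early exaggeration, momentum descent,
deterministic per seed. It is a visualization contract — the tests check
neighborhood preservation (trustworthiness ≥ 0.8 and k-means purity ≥ 0.9 on
well-separated blobs), not any particular layout.

## Metaclustering

Samples (not single cells — the package consumes frequency tables, and the
composition percentages it reports are fractions of samples) are clustered
with a self-organizing map: z-standardized features, codebook initialized
from randomly drawn samples, online Kohonen updates with learning rate
decaying linearly from 0.5 and a Gaussian grid neighborhood whose radius
shrinks from half the grid diagonal to 1 (σ = radius/2, truncated at the
radius, so the map sharpens as training proceeds). Codebook vectors are then
merged by average-linkage hierarchical clustering cut at k (default 4×4
grid, k = 8, 50 epochs in the pipeline), and metaclusters are renumbered
MC1..MCk by descending training-sample occupancy so labels are deterministic
given data and seed. Group compositions, percentage-point composition
differences with percentile-bootstrap CIs (default 1000 resamples within
group), per-metacluster marker volcano tables (FDR family = features within
one metacluster; undersized metaclusters flagged, never silently zero), and
metacluster-to-IDS weights (point-biserial correlation between membership
and IDS) complete the stage.

## Clinical clustering

Binary clinical rows are compared with Jaccard distance; two patients with
no recorded findings are identical under this feature set, so the distance
between all-zero rows is 0 by convention. Rows with missing domains are
excluded and reported. PAM is the canonical clusterer because Jaccard
distances are non-Euclidean; instances small enough to enumerate
(`choose(n, k)` up to 20 000 medoid sets, which covers clinical cohorts of
the size this package targets) are solved exactly, larger ones by BUILD +
SWAP, with every tie broken by the lowest index. Classical MDS provides the
2D view. For k = 3, clusters are tiered mild/moderate/severe by mean CDS
(ties broken by cluster size, larger = more severe) — a data-driven rule in
place of narrative assignment. Feature importance permutes one binary
column at a time, re-runs the clustering, and reports the mean
`1 - ARI` against the original partition.

## Validation layer

* **ROC/AUC** uses the Mann–Whitney convention (half credit for ties),
  DeLong 95% intervals (deterministic, no bootstrap noise), and a Youden
  threshold found by exhaustive search over empirical cutpoints.
* **Composite severity models** on (Pro_mean, Anti_mean, IDS, ΔIDS) come in
  two kinds: one-vs-rest logistic (per-class binomial GLMs, probabilities
  renormalized to sum to one) and random forest. Permutation importance is
  mean decrease in accuracy.
* **Calibration** uses equal-count decile bins (sizes differ by at most
  one) and an intercept/slope from a logistic fit of the outcome on the
  logit of the prediction; predictions at exactly 0/1 are clipped to
  [1e-6, 1 − 1e-6] and the clipping is reported; constant predictions leave
  the slope flagged undefined.
* **Decision curves** report net benefit
  $TP/n - (FP/n)\,p_t/(1-p_t)$ against treat-all and treat-none.
* **Internal validation** implements the bootstrap optimism correction
  (default 500 resamples, honoring the ≥500 floor; failing resamples are
  skipped and counted) and repeated stratified 10-fold cross-validation
  (k reduced with a warning when the smallest class is smaller than k). On
  null data the corrected AUC centres near 0.5 with a small residual
  positive bias at very small n (about +0.05 at n = 40 with four
  predictors, reproduced by the test suite's tolerance of ±0.07) — a known
  property of the correction, reported rather than hidden.

The compositional balance search is a simplified greedy re-implementation:
log-contrast scores (mean log numerator minus mean log denominator),
initialized with the best single pair by cross-validated AUC and grown one
variable at a time until `maxVars` or until the improvement is below
tolerance. The *reported* criterion is a nested cross-validation estimate —
the entire search is repeated inside each training fold and scored on the
held-out fold — because the selection-time CV-AUC is optimistic by
construction (about 0.7 on pure noise at n = 60 with eight candidates,
versus ~0.5 for the nested estimate).

## Determinism and numerical choices

Every stochastic operation takes an explicit seed and routes all randomness
through it; no function perturbs the caller's RNG state. The pipeline writes
plain-text artifacts whose bytes are identical across runs with the same
cohort, configuration and seed; the timestamp lives in a separate manifest.
Correlation targets are validated for positive semi-definiteness
(eigenvalue floor −1e−8) before use; the planted-correlation square root
uses the symmetric eigendecomposition, so draws are reproducible and exact
for rank-deficient targets. Degenerate inputs fail loudly: one-class
outcomes, constant control SDs, constant partitions, out-of-range
frequencies and non-binary clinical codes are errors, while undefined
statistics inside otherwise-valid analyses (constant subsets, undersized
metaclusters, all-or-nothing metacluster memberships) are flagged `NA`.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
cohorts of 39/17 (study conditions) for scoring and clinical stages, 500
per group for correlation-flip recovery, 200 samples for the balance
search fixture, 60–150 samples for SOM/embedding blob recovery, n = 5000
for calibration recovery, and n = 40 with four predictors for the null
internal-validation scenarios. These sizes put every statistical check in a
regime where the expected behavior is sharp while keeping a full run in the
low minutes on one CPU.

## Known limitations

* The sample-level (not per-cell) reading of metaclustering is a design
  choice; per-cell clustering of FCS events is out of scope.
* The severity tiers and metacluster labels are data-driven and carry no
  fixed biological annotation.
* The IDS panel is configurable but defaults to the six subsets named
  above; whether "memory Breg" should be replaced by another memory
  compartment in a given panel is a user decision, not something the
  package can infer.
* Internal validation is no substitute for external validation on an
  independent cohort; the package provides the machinery, not the evidence.
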