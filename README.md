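# ImmuneBalance

Quantitative immune-balance analysis for post-gated flow-cytometry cohorts.

Patients with inborn errors of immunity (IEI) — and in particular the
subgroup with primary immune regulatory disorders (PIRD) — show a
characteristic cellular imbalance: regulatory populations
(CD4⁺CD25ʰⁱCD127ˡᵒFOXP3⁺ Tregs, transitional and memory regulatory B cells)
contract while inflammatory populations (BCL6⁺ and ICOS⁺BCL6⁺
follicular-helper-like cells, activated CD8⁺CD25⁺ T cells) expand.
`ImmuneBalance` condenses that imbalance into a single biomarker, the
**Immune Dysregulation Score**

```
IDS = log( GM(BCL6+, ICOS+BCL6+, CD8+CD25+) / GM(Treg, transitional Breg, memory Breg) )
```

(GM = geometric mean over percent-of-parent frequencies, with a small
pseudocount before logs), and surrounds it with the full analysis pipeline:

* per-subset Mann–Whitney group tests with Benjamini–Hochberg FDR control;
* patient-versus-control **delta-correlation networks** (which subset–subset
  associations are weakened, lost or reversed in patients);
* sample-level **SOM metaclustering** with bootstrap forest plots of
  composition differences, per-metacluster marker volcano tables and
  metacluster→IDS weights;
* a binary **Clinical Dysregulation Score** (CDS, default range 0–4) with
  Jaccard/PAM clinical clustering, MDS, severity tiers and permutation
  feature importance;
* a simplified **compositional balance search** (greedy log-contrast
  selection with a nested-CV criterion);
* a TRIPOD-style **validation layer**: ROC with DeLong intervals and Youden
  thresholds, decile calibration with intercept/slope, decision-curve net
  benefit, bootstrap optimism correction (≥500 resamples) and repeated
  stratified 10-fold cross-validation;
* a **synthetic cohort generator** (39 patients / 17 controls by default,
  severity-coupled cellular and clinical effects) so the whole pipeline is
  reproducible and testable without patient-level data.

The central container is `ImmuneCohort`, an S4 class extending
`SummarizedExperiment` (subsets × samples assay of frequencies strictly
inside (0, 100); group labels, binary clinical matrix, optional genetic
labels and latent severity in `colData`).

## Worked example

```r
library(ImmuneBalance)

cfg <- simulationConfig(seed = 1)        # 39 patients, 17 controls
coh <- generateCohort(cfg)
coh
#> ImmuneCohort: 56 samples ( 39 patients / 17 controls ), 12 subsets
#>   subsets: Treg, TransitionalBreg, MemoryBreg, BCL6pos, ICOSposBCL6pos, CD8posCD25pos ...
#>   clinical domains: autoimmunity, chronic_inflammation, lymphoproliferation, malignancy
#>   latent severity available (synthetic cohort)

scores <- computeScoreTable(coh)
head(scores[, c("sampleId", "group", "ids", "deltaIds", "cds", "clinicalZ")], 4)
#>   sampleId   group   ids deltaIds cds clinicalZ
#> 1      P01 patient 0.915    1.069   3      1.25
#> 2      P02 patient 0.833    0.988   0     -1.32
#> 3      P03 patient 1.029    1.183   0     -1.32
#> 4      P04 patient 0.154    0.309   3      1.25

roc <- rocAuc(scores$ids, groupLabels(coh))
#> IDS AUC = 0.926 (95% CI 0.860-0.992)
#> Youden threshold 0.278: sensitivity 0.79, specificity 0.88

cor.test(scores$ids[!is.na(scores$clinicalZ)],
         scores$clinicalZ[!is.na(scores$clinicalZ)])
#> IDS vs clinical z: Pearson r = -0.54 (p = 0.00038, n = 39)

head(compareSubsets(coh)[order(compareSubsets(coh)$q),
                         c("subset", "p", "q", "direction")], 3)
#>             subset        p       q direction
#> 4          BCL6pos 0.000391 0.00469         1
#> 2 TransitionalBreg 0.001818 0.01091        -1
#> 3       MemoryBreg 0.003280 0.01236        -1
```

Each row of the score table is one sample: `ids` is the log-balance
(positive = inflammatory dominance), `deltaIds` the same score centred on
the control mean, `cds` the count of present clinical manifestation domains
(patients only) and `clinicalZ` its z-score over scored patients. Here the
planted inflammatory shift separates patients from controls (AUC 0.93) and
the IDS correlates inversely with clinical burden (r = −0.54), while the
subset-level tests recover the planted directions (BCL6⁺ up, transitional
Breg and memory Breg down) at FDR < 0.05.

The whole chain — scores, tests, embedding, delta network, metaclustering,
clinical clustering, validation — runs with one call and writes plain-text
artifacts:

```r
runPipeline(coh, "out/", seed = 1)
```

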