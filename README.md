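# rsvmcluster

Random-subspace SVM ensembles ("random SVM clusters") for two-group
classification of resting-state fMRI functional connectivity, with
ensemble-driven feature selection and per-region abnormality weights.

## The problem

A resting-state fMRI subject parcellated into the 90 AAL regions yields a
functional-connectivity profile of P = 90·89/2 = 4005 pairwise Pearson
correlations, while clinical cohorts (e.g. Alzheimer's disease vs healthy
controls) typically contain only a few dozen subjects. A single classifier
on all 4005 features is unstable and says nothing about which connections
discriminate. The random SVM cluster attacks both problems at once:

* **Ensemble**: k member SVMs (RBF kernel,
  k(u,v) = exp(−‖u−v‖² / (2γ²)), width γ = 3, hard margin), each trained on
  n bootstrap subjects from the training set and d features drawn at random
  from the pool (defaults k = 500, n = 40, d = 62). A new subject is
  classified by the **majority vote** of the members; validation accuracy is
  Nc/N3, the fraction of correctly voted validation subjects.
* **Feature selection**: members whose individual accuracy exceeds 0.75 are
  pooled; each feature's occurrence count across their subsets ranks the
  "important features" (top 400). Rebuilding the ensemble with member
  features drawn from only the first m ranked features (m swept 70–400)
  locates the **optimal feature set** — the smallest prefix attaining the
  maximum validation accuracy.
* **Region weights**: each selected connection touches two regions; a
  region's weight is its degree in the selected-connection graph
  (Σ weights = 2 × #connections), flagging the most affected regions.

A synthetic cohort generator (multivariate-normal region series with
"planted" group-differential correlations plus observation noise) makes the
whole pipeline testable without access-controlled clinical data. Demographic
comparison utilities (2×2 chi-square without continuity correction, pooled
two-sample t from summary statistics) cover the usual cohort table.

## Worked example

```r
library(rsvmcluster)

spec   <- syntheticSpec(planted_pairs = plantRandomPairs(seed = 1), seed = 1)
cohort <- generateCohort(spec)
cohort
#> Synthetic cohort: 60 subjects ( 25 A / 35 B ), 90 regions, 120 time points; 20 planted connection(s)

report <- runReplication(cohort,
                         runConfig(k = 500, k_values = seq(5, 600, by = 25),
                                   m_values = seq(70, 400, by = 20), seed = 1))
report
#> Random SVM cluster replication report
#>   cluster accuracy (validation): 1.0000 (100.00%)
#>   mean member accuracy: 0.647
#>   k sweep: best k = 80 (accuracy 1.0000)
#>   optimal feature set: first 70 of 400 ranked features (accuracy 1.0000)
#>   top regions: SMA.R, PoCG.R, SFGmed.L, DCG.L, FFG.L

head(topRegions(report$region_weights, min_weight = 3))
#>   index abbreviation                               full_name hemisphere weight
#> 1    20        SMA.R                Supplementary motor area          R      5
#> 2    58       PoCG.R                       Postcentral gyrus          R      4
#> 3    23     SFGmed.L          Superior frontal gyrus, medial          L      4
#> 4    33        DCG.L Median cingulate and paracingulate gyri          L      3
#> 5    55        FFG.L                          Fusiform gyrus          L      3
#> 6    38        HIP.R                             Hippocampus          R      3
```

The report reads as follows: the 500-member ensemble classifies all 18
validation subjects correctly although its individual members average only
0.647 — the vote aggregates many weak, decorrelated opinions. The k sweep
shows the accuracy saturating at small ensemble sizes on this strongly
planted cohort, and the feature-pool sweep maintains perfect accuracy with
member features restricted to the 70 top-ranked connections, whose incident
regions receive the largest weights.

The demographic utilities reproduce the standard cohort-table tests:

```r
chiSquare2x2(12, 13, 15, 20)         # X2 = 0.156, df = 1, p = 0.693
tTestFromSummary(74.59, 7.03, 25,    # t = -1.397, df = 58, p = 0.168
                 77.09, 6.69, 35)
```

Per-subject time series can be read from delimited text
(`readRoiTimeSeries()`, `readCohort()`), converted with
`connectivityFeatures()`, and precomputed feature matrices exchanged with
`writeFeatures()` / `readFeatures()`. A thin command-line wrapper over the
same functions is provided in `inst/cli/rsvmc`.

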