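# alterex

Predicting gene-level genomic alterations — somatic mutations,
amplifications, deletions — from gene expression profiles, and
quantifying how much **gene aggregation** (regulon activity scores,
robust co-expression-cluster averages) buys in robustness when the data
get noisy or shallow.

The package is for computational biologists who want to ask, on bulk or
single-cell RNA-seq: *can a classifier tell carriers of a given
alteration from non-carriers using expression alone, and does that
ability survive noise and read down-sampling?* It provides every stage
as composable functions:

- **Event matrices** — CNV segments are mapped to genes by maximal
  base-pair overlap (`assignGeneCnv`), binarized at |log2| ≥ 0.5
  (`binarizeCnv`); MAF tables are stripped of protein-silent variants
  (`filterSilentMutations`); events are kept when present in 5–95% of
  samples and ≥ 10 carriers (`filterEvents`); hypermodified samples
  (> 0.5% of genome genes altered) are flagged (`flagHypermodified`).
- **Normalization** — median-library scaling + log2 for bulk
  (`normalizeCounts`), ln(1 + 10⁴·count/total) for single cells
  (`normalizeSingleCell`), OLS covariate regression
  (`regressCovariates`), top-variance feature selection
  (`selectTopVariance`).
- **Aggregation** — per-gene z-score signatures (`buildSignature`);
  regulon activity as the signed, √n-scaled mean of target z-scores
  (`regulonActivity`); disjoint co-expression clusters (`clusterGenes`)
  collapsed with the one-step Tukey biweight (`tukeyBiweight`,
  `aggregateClusters`).
- **Perturbation engines** — Gaussian noise on the normalized scale
  (`addGaussianNoise`) and beta-distributed read down-sampling with
  dropout (`downsampleCounts`): each count is multiplied by
  d ~ Beta(α, β), β = 0.1, α = β(f/r)/(1 − f/r), so E[total] equals
  the target read count f while small β produces complete gene
  dropouts.
- **Modeling harness** — stratified 75/25 splits (`splitData`),
  per-event gradient-boosted-tree classifiers with fixed canonical
  defaults (plus logistic/RF/kNN/SVM/LDA behind the same interface;
  `trainEventModel`), AUROC distributions over repeated partitions
  (`repeatedEvaluation`) or bootstraps (`bootstrapEvaluation`).
- **Evaluation** — Mann–Whitney AUROC with half-credit ties (`auroc`),
  paired two-tailed Wilcoxon model comparison (`pairedWilcoxon`),
  robustness-curve tables (`robustnessCurve`), and a CROP-Seq-style
  single-cell benchmark comparing expression vs activity features on
  identical splits (`runCropSeqBenchmark`).
- **Synthetic cohorts** — `simulateCohort` generates
  negative-binomial cohorts with regulon-coupled co-expression, planted
  driver/passenger alterations, CNV segments with dosage effects and a
  synthetic genome; `simulateSingleCell` thins them into cells with
  depth-dependent dropout. All generators are deterministic given a
  seed.

Standard formats are supported throughout: TSV/MTX matrices, SEG, MAF,
BED, regulon and cluster TSVs (`readSeg`, `readMaf`, `readBed`,
`readRegulons`, `readExprMatrix`, `writeCohort`, ...).

## Worked example

Simulate a 200-sample cohort in which one TF's mutation (30%
prevalence) shifts its 50-target regulon by 1 SD, alongside a matched
passenger mutation with no expression effect; then model both events
from expression, and repeat under heavy Gaussian noise with and without
regulon aggregation.

```r
library(alterex)

cfg <- cohortSimConfig(
    nSamples = 200, nGenes = 1000, nTfs = 2, targetsPerTf = 50,
    driverEvents = list(driverEvent("mutation", 0.3, effectSize = 1,
                                    regulon = 1)),
    passengerEvents = list(passengerEvent("mutation", 0.3)),
    seed = 7)
sim <- simulateCohort(cfg)
sim
#> SimulatedCohort: 1000 genes x 200 samples, 2 events, 2 regulons

nm <- normalizeCounts(cohortCounts(sim))
labels <- eventValues(truthEvents(sim))

driver <- repeatedEvaluation(exprValues(nm), labels[1, ],
                             modelSpec(seed = 1), reps = 10)
round(c(mean = driver$mean, sd = driver$sd), 3)
#>  mean    sd
#> 0.892 0.045

passenger <- repeatedEvaluation(exprValues(nm), labels[2, ],
                                modelSpec(seed = 1), reps = 10)
round(c(mean = passenger$mean, sd = passenger$sd), 3)
#>  mean    sd
#> 0.459 0.072
```

The driver is recovered (mean test AUROC 0.89 over 10 train/test
partitions) while the matched passenger stays at chance (0.46) — the
classifier reads real transcriptional consequences, not event
frequency. Now degrade the data and aggregate:

```r
noisy <- addGaussianNoise(nm, sigma = 2, seed = 1)
noisyAct <- regulonActivity(buildSignature(noisy), cohortRegulons(sim))

exprNoisy <- repeatedEvaluation(exprValues(noisy), labels[1, ],
                                modelSpec(seed = 1), reps = 10)
actNoisy <- repeatedEvaluation(noisyAct, labels[1, ],
                               modelSpec(seed = 1), reps = 10)
round(c(expression = exprNoisy$mean, activity = actNoisy$mean), 3)
#> expression   activity
#>      0.661      0.871

pairedWilcoxon(actNoisy$aurocs, exprNoisy$aurocs)
#> $p.value
#> [1] 0.001953125
#> $direction
#> [1] 1
```

Under noise at twice the typical gene SD, per-gene expression models
drop to 0.66 while regulon-activity models — which average the noise
over 50 targets — hold at 0.87; the paired Wilcoxon test (same splits
for both feature modes) confirms the direction.

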