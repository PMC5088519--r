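# sleepwave

Transcriptional dynamics of sleep deprivation and recovery sleep in the
mouse cortex: batch-effect removal, moderated differential expression,
cross-study integration, trajectory clustering and decay-constant
estimation, with a synthetic-data generator that makes the whole chain
testable offline.

## The problem and who this is for

Sleep need accumulates during wakefulness and discharges during sleep;
its electrophysiological index (NREM EEG delta power) decays after sleep
deprivation with a time constant of ~1.3 h in C57BL/6 mice. The
transcriptional side of this process is obscured by two nuisances that
dominate brain expression data: unwanted variation (batch, platform,
laboratory effects) and time-of-day (circadian) expression. `sleepwave`
is for analysts who want to (re)run this style of analysis — on their
own matrices, on public series-matrix files, or on simulated data — with
every stage testable against a known ground truth.

The pipeline: quantile normalization → removal of k factors of unwanted
variation (RUV, negative-control-gene or replicate-sample variant, with
a data-driven scan for k) → empirical-Bayes moderated-t differential
expression against time-matched circadian controls (BH-FDR < 0.01,
positive/negative-control diagnostics) → assembly of per-gene logFC
trajectories over 0–6 h of recovery sleep → hierarchical clustering into
responder classes → per-cluster exponential decay fits

    logFC_t = LA + (logFC_0 − LA) · e^(−t/τd)

with τd the time constant of return toward the lower asymptote LA —
plus local gene-set enrichment (jackknifed exact test, kappa term
clustering) and cross-study integration (identifier harmonization,
expression filter, PCA with variance-explained and covariate
association).

## Worked example

Simulate the default study design — 96 arrays, 10 groups (circadian
controls CC0/CC6/CC7/CC8/CC11, sleep deprivation SD, recovery sleep
RS1/RS2/RS3/RS6), 10,000 genes, 3 latent batch factors — then select k,
adjust, and test the end-of-deprivation contrast:

```r
library(sleepwave)

sim <- simulateSleepStudy(simulationConfig(seed = 42))
sim$dataset
#> SleepExpressionSet: 10000 features x 96 samples
#> groups: CC0(10) CC11(9) CC6(10) CC7(10) CC8(10) RS1(10) RS2(9) RS3(9) RS6(9) SD(10)

scan <- scanK(sim$dataset, sim$controls, k_max = 6)
scan$recommended_k
#> [1] 3                         # the generator's true k

fit <- ruvFit(sim$dataset, k = scan$recommended_k)
de  <- fitModerated(adjustedData(fit), defaultContrasts()[1, ])
de
#> DEResult SD_vs_CC6: 10000 genes, 796 at FDR < 0.01 (d0 = 5.92, s0^2 = 0.0595)

ev <- evaluateDE(de, sim$controls)
c(recall = ev$recall, n_up = ev$n_up, n_down = ev$n_down)
#> recall   n_up n_down
#>      1    496    300
```

796 genes at FDR < 0.01, more up- than down-regulated, and all 50
positive-control genes recovered (`recall = 1`); without adjustment the
recall on this configuration is about 0.5, and about 0.3 at stronger
batch settings. The full pipeline adds circadian flags, trajectory
clustering and kinetics:

```r
run <- runPipeline(pipelineConfig(synthetic = simulationConfig(seed = 42),
                                  seed = 42))
round(unlist(run$kinetics$class_tau), 2)
#>         slow         fast late_induced
#>         2.74         1.17         6.48

run$kinetics$clusters[, c("cluster", "class", "logFC0", "tau_d", "converged")]
#>   cluster        class      logFC0     tau_d converged
#> 1       1         slow  1.37870573  2.847727      TRUE
#> 2       2         fast  1.37037743  1.211661      TRUE
#> 3       3         fast -1.31162183  1.133738      TRUE
#> 4       4 late_induced -0.04999603  6.481425      TRUE
#> 5       5         slow -1.41245868  2.634206      TRUE
#> 6       6         slow -0.04980990 12.000000     FALSE
#> 7       7         slow  0.05043886 12.000000     FALSE
```

Reading this: the seven trajectory clusters split into fast responders
(upregulated cluster 2 and downregulated cluster 3, recovering within
1–3 h; class-average τd = 1.17 h here, fluctuating around the
generating 1.3 h across seeds), slow responders (clusters 1 and 5,
recovering by 6 h; the fitted ~2.7 h understates the generating 4.5 h
because the lower asymptote is approximated by the 6-h minimum — see the
methods vignette), one late-induced cluster (flat through deprivation,
rising at 6 h of recovery), and two flat noise clusters whose fits hit
the search boundary and are flagged unconverged, excluding them from
class averages. `makeFigures(run, sim$controls, dir = "figs")` writes
the PCA, p-value-histogram, volcano, trajectory and count figures.

File-based workflows use the same stages: `loadExpression()` (plain TSV
or GEO series-matrix block), `loadDesign()`, `loadControls()`,
`loadGMT()`, `harmonizeDatasets()` + `filterExpressed()` +
`pcaReport()` for multi-study integration, and `enrichGeneList()` for
annotation of responder gene lists.

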