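# lifemeth

Epigenome-wide analysis of a composite lifestyle index: scoring, DMP/DMR
discovery, outcome association and mediation, with a ground-truth
synthetic-data generator.

## The problem

Single behaviours — smoking, drinking, inactivity, poor diet — each leave
modest marks on blood DNA methylation. Epidemiologists increasingly ask a
combined question instead: does *overall* lifestyle risk associate with
methylation, and does methylation in turn mediate lifestyle's association
with type 2 diabetes (T2DM)? `lifemeth` packages that full analysis chain
for Illumina-450k-style beta values, for analysts who have a phenotype
table, a beta matrix and a probe annotation and want a reproducible,
tested pipeline rather than a one-off script.

The core quantities:

* **Comprehensive lifestyle index (CLI).** Component points
  (0/1/2 each for smoking, alcohol, physical activity, diet quality) are
  summed unweighted to a total on 0–8; totals ≤ 4 define the binary
  high-risk index used as the EWAS exposure.
* **DMPs.** Per probe *j*, fit M_j = β₀ + β₁·CLI + γᵀC + ε (C = age, sex,
  site, cell proportions, batch, array position; optionally BMI), moderate
  the variances empirical-Bayes style
  (s̃²ⱼ = (d₀s₀² + df·s²ⱼ)/(d₀ + df)), map moderated t to z, fit an
  empirical null z ~ N(μ, σ²) to the bulk by a three-component mixture EM,
  and report BH-FDR on the corrected two-sided p-values. Effects are
  reported as Δβ, the high-minus-low-risk difference of mean beta.
* **DMRs.** Bump hunting on beta-scale effects: cluster probes
  (max gap 500 bp), smooth within clusters (centered running mean,
  window 5), call maximal single-sign runs with |smoothed effect| > 0.01
  and ≥ 3 CpGs, then attach a familywise error rate by exposure-label
  permutation: FWER = (1 + #{null max area ≥ area})/(1 + B).
* **Associations.** OR (logistic, T2DM) or slope (linear, FBG/HbA1c) per
  1% methylation, base and covariate-adjusted models, Wald 95% CIs.
* **Mediation.** Product of coefficients a·b (a: CLI→methylation;
  b: methylation→T2DM adjusted for CLI) with percentile bootstrap CI.

Because the cohorts this design targets are typically access-restricted,
the package includes a synthetic-data generator
(`simulateLifemethBundle()`) whose defaults emulate the target study
population (~700 participants, 88.6% never smokers, 61.6% abstainers,
41.7% high physical activity, diet quality 56 ± 6.1, bimodal beta
landscape, 1–3% spiked effects) and whose ground truth makes every stage
testable. See the methods vignette
(`vignettes/lifestyle-methylation-pipeline.Rmd`) for the model details and
design choices.

## Worked example

```r
library(lifemeth)

cfg <- simulationConfig(nSamples = 400, nProbes = 10000, nSpikedProbes = 20,
                        spikeDeltaBeta = 0.05, nSpikedRegions = 1,
                        regionNProbes = 5, regionDeltaBeta = 0.08, seed = 11)
bundle <- simulateLifemethBundle(cfg)
table(bundle$scores$riskLevel)
#> high  low
#>   69  331

dmps <- runDmpEwas(bundle$experiment)
dmps
#> DMPResults: 10000 probes, model 'base', n = 400
#> empirical null: mu = 0.0391, sigma = 0.9796 (lambda 0.991 -> 1.041)
#> probes at FDR < 0.05: 26
```

69/400 participants land in the high-risk stratum (the emulated
population is mostly low risk). The empirical null is essentially clean
here (bias 0.04, inflation 0.98, genomic λ about 1.04 after correction);
26 probes reach FDR < 0.05 — the 20 isolated spiked probes plus probes of
the spiked region. The top rows are the region's probes, with observed
`deltaBeta` around the configured 0.08.

```r
dmrs <- runDmrEwas(bundle$experiment, nPermutations = 200, seed = 11)
dmrs
#> DMRResults: 6 candidate region(s), FWER from 200 permutations
#> regions at FWER < 0.05: 6
#>   Chr      start     end nProbes   area avgDeltaBeta      fwer
#> 1 chr7  1385525 1385976       5 0.4097       0.0821 0.0050
#> ...
```

The top region is exactly the spiked 5-probe span (average beta
difference 0.082 vs the configured 0.08, FWER 1/201); the smaller calls
are isolated spiked probes that fell inside multi-probe clusters and
dragged their smoothed neighbourhood over the 1% cutoff.

```r
med <- bootstrapMediation(
  bundle$scores$index,
  colMeans(betaValues(bundle$experiment)[spikedProbes(bundle$truth), ]),
  SummarizedExperiment::colData(bundle$experiment)$T2DM,
  nBoot = 1000, seed = 11)
med
#> MediationResult — mediator (logistic outcome)
#>   exposure -> mediator (a): +0.05066
#>   mediator -> outcome  (b): -5.26712
#>   indirect a*b: -0.26682  [-1.70460, 1.24221]  p = 0.707
#>   direct: +0.50968  total: +0.24278  (1000 bootstraps, 0 failed)
```

The high-risk group is 5.1 percentage points more methylated at the
spiked probes (path a); the mediator→outcome path is noisy at this
effect size and the bootstrap interval for the indirect effect spans
zero — no evidence of mediation under these generating conditions, which
is the correct read: the default outcome links are deliberately weak.
With published path coefficients as direct inputs,
`indirectEffect(-0.008, -0.28)` returns `0.00224`.

`runPipeline(bundle$experiment, "out/")` chains all five stages and
writes one TSV per stage (plus a BED for regions and JSON metadata
sidecars with seed and config hash).

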