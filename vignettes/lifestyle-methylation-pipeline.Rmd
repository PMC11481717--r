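---
title: "Methods: lifestyle-index EWAS, region detection and mediation"
author: "lifemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifestyle-index EWAS, region detection and mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifemeth)
```

# Overview

`lifemeth` implements an analysis chain that asks whether combined
modifiable lifestyle risk — rather than any single behaviour — leaves a
detectable mark on blood DNA methylation, and whether that mark in turn
relates to type 2 diabetes (T2DM). The chain has five stages:

1. **Lifestyle scoring.** Four behaviours (smoking, alcohol, physical
   activity, diet quality) are each scored 0/1/2 and summed into a
   comprehensive lifestyle index (CLI) on 0–8, dichotomized at ≤ 4 into a
   binary high-risk indicator.
2. **Differentially methylated positions (DMPs).** Per-probe linear models
   of M-values on the binary index with covariate adjustment,
   empirical-Bayes variance moderation, empirical-null bias/inflation
   correction, and Benjamini–Hochberg FDR.
3. **Differentially methylated regions (DMRs).** Bump hunting on
   beta-scale effects: probe clustering, within-cluster smoothing,
   candidate calling at a 1% methylation-difference cutoff, and a
   permutation familywise error rate.
4. **Outcome association.** Logistic (T2DM) and linear (fasting glucose,
   HbA1c) regressions of the outcomes on top-probe methylation and on the
   lifestyle scores, per 1% methylation or inverse-normal transformed.
5. **Mediation.** Product-of-coefficients decomposition of the CLI→T2DM
   effect through methylation, with percentile bootstrap intervals.

Because the cohort data this design targets are access-restricted, the
package ships a first-class synthetic-data generator with known ground
truth; every stage is validated against that truth and against independent
closed-form oracles.

# The lifestyle index

Each component is scored so that 0 marks the highest-risk category:
current/former/never smoking map to 0/1/2; alcohol is scored against
sex-specific optimal-intake cut-offs (at most 1 unit/day for women, 2 for
men; abstainers score 2); physical activity uses the IPAQ three-level
categorization from MET-minutes/week; diet quality cuts the 0–100 DQI-I
score at fixed thirds of its range (0–33.33 / 33.34–66.66 / above). The
index is the unweighted sum; the interval [0, 4] — including the boundary
total of 4 — is high risk (binary index 1), (4, 8] is low risk.

Two conventions deserve flagging:

* **Day-slot counting.** The IPAQ "7 or more days of any combination" and
  "5 or more days" clauses are operationalized as the *sum* of per-type day
  counts (`vigorousDays + moderateDays + walkingDays`), so a day featuring
  two activity types counts twice. This is IPAQ's own scoring convention;
  records are not granular enough to de-duplicate calendar days.
* **Fixed diet tertiles.** The DQI-I thirds are fixed cut points of the
  score range, not empirical tertiles of the sample at hand. With a
  realistic score distribution (mean 56, SD 6.1) virtually the whole cohort
  sits in the middle band, which is why diet contributes little variance to
  the index — visible in `correlateComponents()` output.

Missing lifestyle values are rejected rather than imputed: imputation
belongs upstream of this package.

# What the synthetic cohort emulates

`simulationConfig()` defaults are fixed study conditions, not tuning
knobs. They emulate a West-African migrant cohort of about 700 adults:
category frequencies for smoking (never/former/current =
88.6/9.1/2.2%), alcohol (abstainer/moderate/heavy = 61.6/35.5/2.9%) and
activity (high/moderate/low = 41.7/22.9/35.5%); DQI-I as a truncated
normal 56 ± 6.1 on [0, 100]; age 51 ± 9.9 years; 42.6% male; three study
sites in the observed proportions; BMI 27 ± 5.5 kg/m²; Dirichlet-drawn
blood-cell proportions around typical leukocyte composition; and
categorical hybridization-batch and array-position covariates. Activity
records are constructed to be internally consistent with the drawn IPAQ
category, so the scorer recovers the generating category exactly — that is
what makes the phenotype stage an oracle for the scoring stage.

Methylation uses a two-layer model. Probe *means* are drawn from a
two-component Beta mixture (Beta(2, 10) and Beta(10, 2), equal weights),
which reproduces the bimodal low/high-methylated landscape of methylation
arrays. Per-sample values then vary around the probe mean as
Beta(μφ, (1−μ)φ) with precision φ = 200, giving a within-probe SD of
roughly 2–4% — the scale actually seen on arrays after normalization. A
single-layer model (each value drawn independently from the bimodal
mixture) was rejected because it implies within-probe SDs above 10%, an
order of magnitude noisier than real arrays, which would make the
published effect sizes (1–3% beta differences) undetectable at any
realistic cohort size.

Spiked probes and regions receive mid-range baseline means (Beta(8, 8))
plus an additive beta-scale shift in high-risk participants — 0.02 by
default for isolated probes (the reported DMP scale), 0.075 for the
default 10-probe region (the reported region-level average difference).
Means are clipped to [1e-3, 1−1e-3] and values to [1e-6, 1−1e-6]; with
mid-range baselines the clipping is essentially never active, which is why
recovered group differences match the configured shift to well within
±0.01. Region probes are written into the annotation at gaps below 200 bp
so they form a single probe cluster downstream; background gaps are a
mixture (30% short, 70% 2–20 kb) so some null clusters exist — without
them the permutation null for regions would be trivially easy.

Outcomes follow the association stage's own model family: T2DM from a
logistic model on the binary index and the centred mean beta over spiked
probes, glucose and HbA1c from linear models plus Gaussian noise (SD 1
mmol/L and 8 mmol/mol). Default link coefficients echo the reported
association scale (CLI log-odds 0.25; 0.29 mmol/L and −1.8 mmol/mol per
1% methylation; intercepts giving ~40% prevalence, 5.3 mmol/L, 38
mmol/mol). One master seed derives three sub-seeds (participants,
methylation, outcomes), so each stage is independently reproducible.

What the generator does *not* emulate: probe-type chemistry (Type I/II),
genetic (mQTL) structure, correlated probes outside spiked regions,
cell-type-specific methylation, and missing data. Passing tests therefore
demonstrate correctness of the statistical machinery under a clean,
exchangeable null — not robustness to every artefact of real arrays.

# The DMP stage

Statistics are computed on M-values, `log2(beta/(1-beta))` with beta
clipped at ε = 1e-6, because M-values are closer to homoscedastic; effect
sizes are reported as beta-scale group differences, which read directly as
methylation percentages. The design matrix holds the intercept, the binary
index, age, sex, site indicators, cell proportions (one type dropped as
the reference, since proportions sum to one), and batch/array-position
indicators (first level dropped); an optional secondary model adds BMI.
Rank deficiency is an error that names the collinear columns.

Per-probe ordinary least squares is vectorized through one shared QR
decomposition. Variances are moderated empirical-Bayes style: a scaled
inverse-chi-square prior (d₀, s₀²) is fitted to the residual variances by
method of moments on log variances (the trigamma inverse solved by
Newton's method), posterior variances are
(d₀s₀² + df·s²)/(d₀ + df), and moderated t statistics get df + d₀ degrees
of freedom. The limits behave as expected — d₀ = 0 reproduces the ordinary
t, d₀ = ∞ a common variance — and the estimates agree with the established
implementation in `limma::squeezeVar`, which the test suite uses as an
independent cross-check only.

Moderated t statistics are mapped to z-scores through their tail
probabilities (computed on the log scale to avoid underflow), and the bulk
of the z distribution is fitted with a three-component normal mixture EM —
a dominant central null component flanked by one negative- and one
positive-mean component for true signal. The central mean and SD are the
bias and inflation estimates; corrected statistics are (z − μ)/σ. The EM
is deterministic (median/MAD initialization, tails started two null-SDs
out, tail means constrained to their side of the null mean, SD floor
1e-3, tolerance 1e-6, at most 1000 iterations) and falls back to
median/MAD with a warning if it fails to converge. A Gibbs-sampler
formulation of the same estimand exists in the literature; the EM was
chosen because it is deterministic and fast at desk scale. Final p-values
are two-sided normal tails of the corrected statistics, adjusted by an
in-package Benjamini–Hochberg step-up (cross-checked against a brute-force
quadratic-time oracle and against `p.adjust`), with FDR < 0.05 the
genome-wide significance convention.

# The DMR stage

Region detection deliberately works on the *beta* scale so that the 0.01
candidate cutoff literally means a 1% methylation difference. Probes are
clustered at a 500 bp maximum gap (the usual bump-hunting convention — the
method description this stage follows does not state the value, so it is
exposed as a parameter), effects are smoothed within clusters by a
centered running mean (window 5, truncated at cluster edges; clusters
under 3 probes pass through), and candidates are maximal single-sign runs
above the cutoff with at least 3 probes — the definitional floor for a
region.

Significance is a permutation familywise error rate: exposure labels are
re-assigned at random with covariates held fixed, the entire
effect–smooth–call pipeline is re-run per permutation (implemented via
Frisch–Waugh residualization, so all permutations reduce to one matrix
product), and each candidate's FWER is the add-one estimator
(1 + #{null max area ≥ area})/(1 + B), which cannot return zero. B = 500
by default. Label permutation (rather than a residual bootstrap) was
chosen as the null-generation scheme: it is exact under exchangeability of
the exposure given covariates, which holds by construction in the
synthetic conditions; with covariates the null is approximate. The
original description of this analysis says only "bootstrap", so this is a
documented design choice, not an inferred detail.

# Outcome association and mediation

Association models are routine epidemiology and are fitted with R's
`glm`/`lm` (IRLS at tolerance 1e-8, max 100 iterations; Wald intervals).
Two predictor scalings are supported and recorded side by side, because
the reporting convention this stage mirrors transforms methylation
predictors to normal quantiles *and* phrases effects "per 1% increase":
`per_1pct` multiplies beta by 100 (slopes divide by exactly 100, a tested
identity), `inverse_normal` applies the Blom rank transform
Φ⁻¹((r − 3/8)/(n + ¼)). The default report uses per-1% effects; p-values
from either scaling can be compared. Perfect separation in the logistic
model is detected (diverging coefficient) and raised as an error rather
than reported. No multiplicity correction is applied across the small
candidate set — these are nominal follow-up p-values.

Mediation is the product-of-coefficients decomposition: a (exposure →
mediator, linear), b and the direct effect (outcome ~ exposure + mediator,
logistic for T2DM), total (outcome ~ exposure). The indirect effect is
a·b; with a logistic outcome a and b live on different scales (beta units
and log-odds), so the product is scale-hybrid — interpretable as a test of
mediation but not as a risk difference. In the all-linear case
total = direct + indirect holds to numerical precision and is tested.
Intervals are percentile bootstrap over participants (B = 1000 by
default, seed-deterministic), chosen over BCa to match the simple
bootstrap this analysis convention describes; failed replicate fits are
dropped and counted, with more than 10% failures an error.

# Numerical choices and degenerate inputs

* M-transform clipping ε = 1e-6; transforms are finite at beta 0 and 1.
* Zero-variance probes get coefficient 0 and variance 0; they do not
  break moderation (the prior fit uses positive variances only).
* If all variances are identical the prior degrees of freedom are
  reported infinite and every posterior variance equals s₀².
* Zero-variance columns in the component correlation matrix yield `NA`
  with a warning naming the column.
* The FWER add-one estimator bounds every reported value in
  [1/(B+1), 1].
* All randomized stages (generator, permutations, bootstrap) take
  explicit integer seeds; equal seeds give byte-identical output files.

# Validation problem sizes

The test suite validates the chain at sizes chosen to make the checks
sharp but quick: null calibration of the DMP stage on 20 datasets of
10,000 probes × 400 samples (uniform raw p by Kolmogorov–Smirnov, applied
per dataset with a ≥ 95% pass rule; post-correction genomic inflation λ
within [0.9, 1.1]; minimum FDR above 0.05 in ≥ 95% of datasets); full
recovery of 20 spiked probes (Δβ = 0.05, n = 400) inside the top 40 at
FDR < 0.05; region-level FWER calibration on 50 null datasets of 2,000
probes × 200 samples at B = 200 with power checked on a spiked 5-probe
region (Δβ = 0.08, B = 100, ≥ 80% probe overlap); empirical-null recovery
from 20,000 simulated statistics with bias 0.5 and inflation 1.5;
bootstrap coverage of the null indirect effect over 50 datasets
(n = 300, B = 200). Estimator-level checks run against independent
oracles: the normal equations for per-probe least squares, a brute-force
BH, the 2×2 cross-product odds ratio, and hand-computed Blom scores.

# Limitations

The probe-level model assumes an exchangeable exposure given covariates
and independent probes outside regions; real arrays violate both to some
degree, and the empirical-null correction absorbs only the bulk-level
consequences. The region FWER conditions on candidates from the observed
data, so it is a familywise rate for the observed candidate set, not a
selective inference guarantee. The scale-hybrid logistic indirect effect
should be read qualitatively. And all power statements here are statements
about the synthetic conditions above — a cohort with different noise or
confounding structure will differ.
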