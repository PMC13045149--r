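---
title: "Habitat imaging of renal tumors from triphasic CT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat imaging of renal tumors from triphasic CT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitatCT)
```

## The problem

Clear cell renal cell carcinoma (ccRCC) is graded histologically on the
WHO/ISUP four-tier scale; grades I–II (low) and III–IV (high) differ in
prognosis and management. Preoperative grading by needle biopsy samples a
single locus of a spatially heterogeneous tumor and can misclassify.
*Habitat imaging* instead partitions the whole tumor into subregions
("habitats") with similar contrast-enhancement kinetics across the three
phases of a triphasic CT exam — corticomedullary (CMP), nephrographic (NP)
and excretory (EP) — and summarizes each tumor by the volume fraction of
each habitat. Those fractions, combined with simple clinical covariates,
feed a logistic nomogram for the probability of high grade.

`habitatCT` implements that pipeline end to end: voxel pooling, K-means
habitat mapping with elbow-based selection of the number of habitats,
volume-fraction quantification, screened + stepwise logistic modeling, and
discrimination / calibration / clinical-utility evaluation. Because patient
imaging of this kind is not publicly depositable, the package ships a
synthetic phantom and cohort generator with the same statistical structure,
so every stage is testable without any download.

## The habitat model

Each tumor voxel contributes a triplet
$x_i = (\mathrm{HU}_{CMP}, \mathrm{HU}_{NP}, \mathrm{HU}_{EP})$. Voxels
from the modeling cohort are pooled into one $N \times 3$ matrix and
partitioned by K-means, minimizing

$$SSE(k) = \sum_{i=1}^{N} \lVert x_i - \mu_{c_i} \rVert^2 ,$$

where $\mu_{c_i}$ is the centroid of the cluster containing $x_i$.
`kmeansFit()` runs Lloyd iterations from k-means++ starts, keeps the best
of `nInit = 10` restarts by SSE, re-seeds empty clusters at the point
farthest from its centroid, and stops when the largest centroid shift
falls below `tol = 1e-4` HU or after `maxIter = 300` iterations. All
randomness flows through R's RNG, so a seed fixes the fit exactly. The
per-patient habitat volume fraction is

$$F_i = \frac{\#\{\text{voxels in habitat } i \text{ within the VOI}\}}
             {\#\{\text{voxels within the VOI}\}},$$

stored as a decimal in $[0,1]$; multiply by 100 only for display.

### Choosing the number of habitats

The elbow criterion is stated informally in most applied work ("the point
where the SSE decline flattens"). `elbowPoint()` formalizes it: both axes
of the $(k, SSE)$ curve are min–max normalized to $[0,1]$ and the selected
$k$ maximizes the perpendicular distance to the chord joining the curve's
endpoints; ties break toward the smaller $k$, so an exactly linear curve
returns the smallest candidate. The default candidate range is
`kRange = 2:8`. We deliberately exclude $k = 1$: a one-cluster "partition"
is not a segmentation, and because $SSE(1)$ is the total variance it
dwarfs the rest of the curve — including it makes the initial drop dominate
the chord geometry and biases the elbow downward by one. On pooled voxels
simulated from the package's default four-habitat kinetics, the 2–8 range
recovers $k^\* = 4$ in every seed we have run.

### Canonical habitat order

K-means labels are arbitrary, so `canonicalizeModel()` fixes a convention:
habitats are ordered by strictly descending CMP centroid (ties by NP, then
EP). Habitat 1 is therefore always the strongly early-enhancing subregion
(well-perfused, washing out by EP) and the last habitat the persistently
hypo-enhancing one. This ordering is a convention of this package — the
numbering in any particular study is reproducible only up to such a rule.

### Clustering scope

`fitCohortHabitats(scope = "train_only")` (default) fits centroids on
training-cohort voxels only. `scope = "all_patients"` pools validation
voxels too — a convention some studies use — and emits an explicit
information-leakage warning, because centroids fitted on validation voxels
make downstream validation metrics slightly optimistic.

## The grading model

Candidate predictors (clinical covariates plus $F_1..F_{k-1}$; the last
fraction is omitted because fractions sum to one) pass through:

1. **Univariate screen** (`univariateScreen()`): one single-predictor
   logistic fit each; predictors with Wald $P < 0.1$ are retained. The
   lenient 0.1 threshold is the standard guard against discarding
   clinically relevant variables too early.
2. **Backward stepwise** (`stepwiseBackward()`): from the full model,
   repeatedly drop the predictor with the largest likelihood-ratio-test
   $P \ge 0.10$ and refit, until all survivors test below 0.10. This
   mirrors the Backward:LR procedure of mainstream statistical packages;
   the threshold is configurable. The removal path is recorded.
3. **Nomogram** (`buildNomogram()`): each predictor's contribution
   $\beta_j x_j$ over its observed range is rescaled so the largest
   $|\beta_j| \cdot \mathrm{range}_j$ spans exactly 0–100 points; the
   points total maps back to probability through the reconstructed linear
   predictor, so `nomogramPredict()` reproduces the logistic prediction
   exactly (tested to 1e-9).

Logistic fitting itself is delegated to `stats::glm` (IRLS, observed-
information covariance) behind `fitLogistic()`, which adds input
validation and separation detection: fits whose probabilities hit 0/1
numerically are flagged rather than silently reported. Coding
conventions: grade high = 1, sex male = 1, fractions as decimals.

## Evaluation

- `rocAuc()` computes the Mann–Whitney AUC (ties count 1/2) with DeLong
  structural-component variance; the 95% CI is $\pm 1.96\,SE$, clipped to
  $[0,1]$ (an unclipped Wald bound can exceed 1 in small samples; we clip
  and say so).
- `delongTest()` is the paired DeLong comparison, exposing the full 2×2
  covariance of the two AUCs. Comparing a model with itself returns
  $z = 0,\ p = 1$ with a warning instead of 0/0.
- `hosmerLemeshow()` bins subjects by predicted-probability deciles
  (default 10 groups; tied probabilities stay together; bins with zero
  expected count merge with a neighbor) and uses $df = g - 2$. That df
  convention is calibrated for *fitted* models — the setting in which the
  test is defined; for externally fixed probabilities the statistic is
  approximately $\chi^2_g$ and the test with $g-2$ df over-rejects, so the
  package's simulations (and the test suite) evaluate it on fitted
  probabilities.
- `decisionCurve()` computes net benefit
  $NB(t) = TP/n - FP/n \cdot t/(1-t)$ over thresholds 0.01–0.60 (step
  0.01 by default), a range that covers plausible treatment thresholds for
  a grading decision, with treat-all and treat-none references.
- `iccAgreement()` is fixed to ICC(2,1) — two-way random effects, absolute
  agreement, single measure — with the conventional "good agreement" flag
  at 0.85. Studies often report "ICC" without specifying the form; this
  package documents its choice rather than guessing per call.
- `stratifiedSplit()` draws the 7:3 train/validation split stratified by
  grade; the *total* training size is exactly `round(0.7 n)`, allocated
  across strata by largest remainder (per-stratum rounding alone can
  overshoot the total by one).

## The synthetic generator

`generatePhantom()` builds an ellipsoidal tumor on a regular grid
(default spacing 1 × 1 × 3 mm, the analysis grid), lays out spatially
coherent habitat subregions and draws per-voxel HU values independently
per phase from each habitat's Normal kinetics. The default kinetics are
the package's four-habitat reference parameter set (mean ± SD HU per
phase, canonical order), with habitat 1 at CMP 148.776 ± 31.368 HU down
to habitat 4 at CMP 36.851 ± 18.669 HU.

Design choices worth knowing:

- **Spatial coherence.** Real habitats are contiguous blobs, not
  salt-and-pepper voxels. Each habitat gets a seeded Gaussian random field
  (white noise low-pass filtered at the `coherence` scale, default 4 mm);
  habitats claim their apportioned voxel counts where their field is
  highest. Composition targets are met *exactly* (largest-remainder
  apportionment), and `coherence = 0` degenerates to spatially independent
  labels.
- **Cohort structure.** Per patient: grade ~ Bernoulli(88/272); habitat
  composition ~ Dirichlet around the grade's center (low grade
  (0.209, 0.365, 0.259, 0.167); high grade ∝ (0.068, 0.393, 0.317,
  0.221)) with concentration 20, which yields per-patient fraction SDs of
  order 0.05–0.1; sex ~ Bernoulli(0.606 / 0.841 by grade); maximum
  diameter ~ Normal(43.46, 14.22) / Normal(60.98, 26.35) mm by grade,
  truncated at 12 mm. The Dirichlet form is an assumption — per-patient
  fraction distributions are rarely published beyond mean ± SD — and the
  concentration is deliberately a single overridable knob.
- **What is not emulated.** Scanner physics, beam hardening, contrast
  pharmacokinetics, registration error, segmentation variability, and
  within-habitat spatial HU correlation. Passing tests on these phantoms
  demonstrates the *statistical machinery* (recovery of known structure,
  calibration of the tests, determinism), not robustness to real-world
  acquisition artifacts.

## Known numerical limitations

**Extreme-centroid bias under re-simulation.** The reference habitat
parameters are cluster-member statistics (means and SDs of voxels *after*
a K-means partition). Simulating full Gaussians with those SDs recreates
more between-habitat overlap than the original mixture had: the tails
that K-means had cut off are regrown. Re-clustering such a simulation
therefore recovers interior centroids well (within a few HU) but biases
the most extreme centroid outward — in our 200,000-voxel simulations the
highest-CMP centroid comes back near 158 HU against a generating mean of
148.8, a ~+10 HU truncation bias, while the lowest-CMP centroid is
recovered within ~1 HU. This is a property of simulating from truncated
cluster statistics, not of the clustering code; the test suite documents
it rather than hiding it.

**Elbow geometry.** The chord-distance formalization is one of several
reasonable elbow rules; its selections depend mildly on the candidate
range endpoints (see above for why the range starts at 2).

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen to make the statistical
assertions sharp while keeping a full run in a few minutes on one CPU:
200,000 pooled voxels × 10 seeds for elbow/centroid recovery, cohorts of
190–1,000 table-level patients for the modeling properties (50 seeded
replicates for selection recovery), 500 replicates of n = 2,000 for the
Hosmer–Lemeshow size check, and 60-patient volumetric cohorts for the
end-to-end pipeline. Exhaustive-enumeration oracles (all partitions, all
pairs) back the K-means, AUC and DeLong components on small instances.

## Reproducibility

Every stochastic stage takes an explicit seed; `runPipeline()` expands one
root seed into per-stage seeds and writes every artifact (config, cohort
table with fractions, habitat model JSON, screen table, fit and nomogram
JSON, evaluation JSON, DCA curves, report) into one run directory. Two
runs with the same configuration produce byte-identical artifacts — this
is asserted in the test suite.
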