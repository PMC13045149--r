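# habitatCT

Habitat imaging of clear cell renal cell carcinoma (ccRCC) from triphasic
contrast-enhanced CT, for preoperative WHO/ISUP grade stratification.

Radiologists and imaging scientists who have, per patient, three
co-registered CT volumes — corticomedullary (CMP), nephrographic (NP) and
excretory (EP) phase — plus a binary tumor VOI mask can use this package
to:

1. pool all tumor voxels into an `N × 3` Hounsfield-unit matrix,
2. partition them into enhancement **habitats** by seeded K-means, choosing
   the number of habitats with an elbow rule on the within-cluster sum of
   squared errors
   `SSE(k) = Σᵢ ‖xᵢ − μ_cᵢ‖²`,
3. quantify each tumor by its habitat volume fractions
   `Fᵢ = (# voxels in habitat i within VOI) / (# voxels within VOI)`,
4. combine fractions with clinical covariates (sex, maximum diameter, …)
   in a logistic model selected by a univariate screen (P < 0.1) plus
   backward likelihood-ratio stepwise elimination (P ≥ 0.10 removed), and
   present it as a 0–100-point nomogram, and
5. evaluate it: Mann–Whitney AUC with DeLong variance and paired DeLong
   tests, Hosmer–Lemeshow calibration, decision-curve net benefit
   `NB(t) = TP/n − FP/n · t/(1−t)`, and ICC(2,1) for segmentation
   reproducibility.

Because cohorts of this kind are not publicly depositable, the package
includes a synthetic phantom/cohort generator (`generatePhantom()`,
`generateCohort()`) that reproduces the statistical structure the analysis
assumes — ellipsoidal tumors with spatially coherent habitat subregions,
grade-conditional habitat composition, sex and diameter distributions — so
the entire pipeline is testable end to end. See the methods vignette
(`vignettes/habitat-imaging.Rmd`) for the model, conventions and known
limitations.

## Worked example

Simulate pooled tumor voxels from the package's four-habitat reference
kinetics, select the number of habitats, and fit the habitat model:

```r
library(habitatCT)

vox <- simulateHabitatVoxels(50000, seed = 1)
sel <- selectKElbow(vox$values, nInit = 5, seed = 2)
sel$kStar
#> [1] 4

fit <- kmeansFit(vox$values, 4, nInit = 10, seed = 3)
can <- canonicalizeModel(fit$model, fit$assignments)
can$model
#> HabitatModel: k = 4 habitats (canonical order)
#>   SSE = 66326858 on 50000 voxels
#>        CMP      NP      EP
#> H1 158.672 145.107 114.783
#> H2  95.504 114.772 100.923
#> H3  57.237  76.222  71.713
#> H4  35.729  29.166  32.262

round(habitatFractions(can$assignments, 4), 4)
#>     F1     F2     F3     F4
#> 0.2041 0.2775 0.2993 0.2191
```

Habitat 1 (strong corticomedullary enhancement, washing out by the
excretory phase) is canonically first; the persistently hypo-enhancing
habitat is last. The recovered centroids sit close to the generating
kinetics (the extreme CMP centroid is biased outward by design of the
simulation — see "Known numerical limitations" in the vignette).

The full study workflow — synthetic cohort, resampling to the
1 × 1 × 3 mm analysis grid, stratified 7:3 split, habitat model on
training voxels, fractions, screen + stepwise selection, nomogram,
evaluation — runs from one seeded configuration:

```r
res <- runPipeline(defaultPipelineConfig(seed = 11))
#> [cohort] generating 60 patients
#> [resample] target spacing 1 x 1 x 3 mm
#> [split] 42 training / 18 validation patients
#> [cluster] k = 4 habitats, SSE = 1466127545
#> [screen] retained: diameterMm, F1
#> [stepwise] final model: diameterMm, F1
#> [evaluate] training AUC = 0.826, validation AUC = 0.9

oddsRatios(res$fit)
#>     variable    beta    se    OR ciLow ciHigh      p
#> 1 diameterMm   0.038 0.020 1.038 0.999  1.079 0.0533
#> 2         F1 -16.463 6.724 0.000 0.000  0.037 0.0144
```

Larger tumors carry higher odds of high grade; a larger fraction of the
well-perfused habitat 1 carries lower odds — the grade-conditional
structure the generator encodes and the model recovers. The run directory
(`res$outDir`) holds every artifact (cohort CSV with `F1..F4`, habitat
model JSON, screen table, fit and nomogram JSON, evaluation JSON, DCA
curves, a markdown report); two runs with the same configuration are
byte-identical.

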