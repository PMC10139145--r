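# tfdp — tear-fluid denaturation profiling by simulated nanoDSF

Tear fluid can be collected non-invasively, and the thermal denaturation
profile of its proteome — recorded by nanoDSF as intrinsic fluorescence at
330 and 350 nm during a 35–95 °C ramp — shows two characteristic derivative
peaks whose positions (T1m, T2m) shift in primary open-angle glaucoma
(POAG). `tfdp` is an R package for researchers developing or stress-testing
this style of thermogram diagnostic. It provides:

* a **mechanistic forward simulator** of melting scans for the five core
  tear proteins (LYZ, LCN1, IGA, HSA, LTF) and their physiological mixtures:
  two-state van't Hoff unfolding, fU(T) = 1/(1 + exp(ΔH(1 − T/Tm)/RT)),
  linear channel superposition, and saturating ligand-induced Tm shifts
  (myristic acid: HSA → 80.3 °C, LYZ → 55.6 °C; Fe³⁺: LTF → 95.0 °C;
  latanoprost: none);
* a **synthetic cohort generator** with known per-subject ground truth,
  defaulting to the published class means — CONTROL (67.9, 77.7) °C,
  POAG-like (64.6, 79.3) °C;
* the **analysis pipeline**: spline alignment to a common grid, the
  six-curve profile (F330, F350, F350/F330 and their temperature
  derivatives via Savitzky–Golay smoothing-differentiation), prominence-based
  two-peak extraction with boundary censoring, two-parameter k-means
  (k = 2, POAG-like = lower-T1m centre), and a stratified 5-fold
  cross-validated benchmark of four classifiers (ridge logistic regression,
  degree-1 polynomial SVM, 500-tree random forest, AdaBoost with 100
  depth-3 trees) on 726 full-curve features, reported as mean accuracy ±
  95% CI with pooled confusion rates.

Everything is S4 with validity checking, seeded end to end, and
bit-reproducible.

## Worked example

```r
library(tfdp)

## a noiseless scan of the healthy tear-relevant mixture
## (140 HSA, 110 LTF, 50 LYZ, 30 IGA, 100 LCN1 ug/mL)
run <- simulateScan(mixturePreset("CONTROL"), noiseSigmaRel = 0)
run
#> NanoDSFRun CONTROL [unlabelled]: 601 points, 35.0-95.0 degC

detectPeaks(sixCurves(run))
#> PeakPair: T1m = 68.3 degC, T2m = 74.6 degC (2 raw candidate(s))
```

The mixture melts in two waves: the low-Tm proteins (LTF 67.4, LYZ 67.8,
LCN1 69.4 °C) merge into the first derivative peak and the high-Tm pair
(IGA 72.9, HSA 75.1 °C) into the second. Simulated alone, each protein's
detected apex equals its melting temperature to 0.1 °C.

```r
## a labelled synthetic cohort at the published cluster averages,
## through peak extraction and two-parameter k-means
ds <- generateCohort(CohortConfig(n = c(CONTROL = 25L, POAG = 25L), seed = 1))
peaks <- extractCohort(cohortRuns(ds))
cl <- kmeansTwo(peaks[peaks$complete, c("t1m", "t2m")], seed = 1)
cl
#> ClusterResult (k = 2)
#>   cluster 1: centre (64.58, 79.44) degC, n = 25  <- POAG-like
#>   cluster 2: centre (67.96, 77.72) degC, n = 25
#>   inertia 68.655 (best of 50 restarts, seed 1)

crossTab(cl, peaks$label[peaks$complete])$positiveFraction
#> CONTROL    POAG
#>       0       1
```

The recovered centres sit on the generating class means — (64.6, 79.3) and
(67.9, 77.7) °C — and at these separations every POAG-like subject lands in
the POAG-like (lower-T1m) cluster. `runCV(assembleFeatures(...))` runs the
four-classifier benchmark on the same runs; `runPipeline()` chains all
stages and writes CSV/JSON artifacts plus a manifest.

## Package layout

| Path | Contents |
| --- | --- |
| `R/thermoModel.R` | species/ligand library, two-state model, scan simulator |
| `R/syntheticCohort.R` | two-peak profile and cohort generators |
| `R/profileIO.R` | CSV I/O, spline resampling, six-curve construction |
| `R/features.R` | peak detection and cohort-level extraction |
| `R/clustering.R` | two-group k-means and contingency reporting |
| `R/classify.R`, `R/adaboost.R` | feature assembly, CV harness, learners |
| `R/pipeline.R` | end-to-end orchestration (`runPipeline`) |
| `inst/cli/tfdp.R` | thin command-line wrapper over the exported functions |
| `vignettes/tfdp-methods.Rmd` | the models, parameter choices and limitations |
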