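---
title: "Tear-fluid denaturation profiling: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tear-fluid denaturation profiling: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfdp)
```

## The problem

nanoDSF (label-free differential scanning fluorimetry) records the intrinsic
tryptophan/tyrosine fluorescence of a protein sample at 330 and 350 nm while
the sample is heated. Unfolding red-shifts the emission, so the ratio
F350/F330 rises through each thermal transition and the derivative
d(F350/F330)/dT shows a peak at each transition midpoint. Tear fluid is
dominated by five proteins — lysozyme C (LYZ), lipocalin-1 (LCN1),
immunoglobulin A (IGA), serum albumin (HSA) and lactotransferrin (LTF) — and
its denaturation profile characteristically shows **two** major derivative
peaks, at temperatures we call T1m (near 65 °C) and T2m (near 78 °C). The
positions of this peak pair shift with disease: in primary open-angle
glaucoma (POAG) the observed population averages move from (67.9, 77.7) °C to
(64.6, 79.3) °C, which makes (T1m, T2m) a candidate screening biomarker.

`tfdp` implements the full desk-side counterpart of that workflow:

1. a **mechanistic simulator** of single-protein and mixture melting scans
   (two-state van't Hoff unfolding, linear signal superposition, ligand-induced
   Tm shifts);
2. a **phenomenological cohort generator** producing labelled patient-like
   two-peak profiles with known ground truth;
3. the **six-curve profile** construction (F330, F350, ratio, three
   derivatives) with spline alignment and Savitzky–Golay
   smoothing-differentiation;
4. **peak detection** reducing the derivative curve to the (T1m, T2m) pair;
5. **two-parameter k-means** clustering of subjects; and
6. a **cross-validated benchmark** of four classifiers (LR, polynomial SVM,
   random forest, AdaBoost) on full-curve features.

## The two-state forward model

Each protein species is a two-state (folded ⇌ unfolded) unfolder with a
temperature-independent van't Hoff enthalpy ΔH. With temperatures in kelvin,

$$\Delta G(T) = \Delta H \left(1 - \frac{T}{T_m}\right), \qquad
  f_U(T) = \frac{1}{1 + e^{\Delta G(T)/(RT)}} .$$

The fraction unfolded is exactly ½ at $T_m$ and the transition scale is
$s = R T_m^2/\Delta H$ (≈ 1.3 °C at 348 K for the default ΔH), giving a
derivative-peak FWHM of $3.53\,s \approx 4.4$ °C. Channel signals superpose
linearly over mixture components $i$ with concentrations $c_i$:

$$F_\lambda(T) = \sum_i c_i\,\bigl(1 + \beta_{\lambda i}(T-35)\bigr)
   \bigl(a_{\lambda i} + d_{\lambda i}\,(2 f_{U,i}(T) - 1)\bigr),$$

with mean emission $a$, unfolding contrast $d$ (sign convention $d_{350} > 0 >
d_{330}$) and baseline drift $\beta$. Multiplicative Gaussian noise
$(1 + \sigma_{rel}\,\varepsilon)$ is applied per point and channel under a
seed; $\sigma_{rel} = 0$ gives a deterministic scan.

### Parameter choices that matter

* **ΔH = 800 kJ/mol (default, per species).** No enthalpies are published
  for this assay, so one shared value is used. The choice is pinned by the
  mixture geometry: the five Tms form a low group (67.4, 67.8, 69.4 °C) and
  a high group (72.9, 75.1 °C) about 6 °C apart. At ΔH = 600 kJ/mol the
  second derivative peak of the physiological mixtures has a topographic
  prominence of only ~1% of the curve range — below any reasonable detection
  threshold — so the mixture profile degenerates to one peak. At 800 kJ/mol
  the second peak's prominence is 13–17% of range for both mixture presets,
  robustly above the 5% default threshold, while the transition width
  (FWHM ≈ 4.4 °C) stays in the range typical of cooperative single-domain
  unfolding.
* **Contrast d = ±0.01 (1% of mean emission).** The ratio of two affine
  functions of $f_U$ is a Möbius function of $f_U$, and its derivative apex
  sits **above** $T_m$ by approximately $2 (d/a)\, s$. At the 5% contrast cap
  this bias is ~0.13 °C — larger than the 0.1 °C reporting precision; at 1%
  it is ~0.03 °C and every library species round-trips its printed Tm
  exactly after rounding. The cost of small contrast is signal-to-noise in
  *noisy* mechanistic scans, which the pipeline's smoothing accommodates
  (below).
* **Ligand binding is saturating.** A ligand modifier replaces (or shifts)
  the Tm of listed species outright: myristic acid maps HSA 75.1 → 80.3 °C
  and LYZ 67.8 → 55.6 °C; Fe³⁺ maps LTF 67.4 → 95.0 °C; latanoprost maps
  nothing. No binding-constant titration is modelled — the underlying
  experiments report only end-state midpoints at fixed ligand excess.

### What the mechanistic model does *not* reproduce

Linear superposition bounds every mixture peak by its component Tms. The
empirically observed mixture behaviour — a T2m at 77.7 °C *above* the highest
component Tm of 75.1 °C, its myristate/iron-induced excursions, and the
90.3 °C iron peak — involves emergent inter-protein interactions and is out
of scope. This is exactly why the cohort generator below is phenomenological:
cohort-level analyses need direct control of (T1m, T2m).

## The phenomenological cohort generator

A patient-like profile is built directly in ratio space:

$$\mathrm{ratio}(T) = b + m\,(T-35)
  + A_1 \Lambda\!\left(\frac{T - T^{1}_m}{w_1}\right)
  + A_2 \Lambda\!\left(\frac{T - T^{2}_m}{w_2}\right),$$

with Λ the logistic CDF; F330 decays linearly and F350 = ratio · F330, then
seeded multiplicative noise is applied to both channels. Defaults: baseline
0.85, slope 0.001/°C, amplitudes $A_1 = 0.18$, $A_2 = 0.24$, scales
$w = 0.9$ °C (FWHM ≈ 3.2 °C), F330 level 2000 RFU with 0.2%/°C quenching and
$\sigma_{rel} = 0.002$. The amplitudes and widths were chosen together with
the smoothing window (next section) so that, as in real patient scans, the
two apexes dominate instrument-level noise: with these settings the detected
peaks of 200 noisy replicates stay within 0.2 °C of the noiseless detection
in ≥ 95% of cases.

A cohort draws per-subject true $(T^1_m, T^2_m)$ from class-conditional
Gaussians — defaults are the published cluster averages, CONTROL (67.9, 77.7)
and POAG (64.6, 79.3) °C, with 0.8 °C SDs (a stand-in; within-cluster spreads
are not published) — rejection-resampling any draw violating
$T^1_m < T^2_m - 4$ °C. Shape parameters are jittered per subject, and every
subject's scan uses a child seed derived from the master seed by a fixed
integer mix ($s_i = (1000003\,s + 7919\,i) \bmod (2^{31}-1) + 1$), so cohorts
are bit-reproducible across platforms.

What the generator deliberately does **not** emulate: capillary artefacts,
aggregation scattering, baseline curvature, three-peak or shoulder profiles,
and any covariate structure (age, sex, treatment). Tests passing on this
generator therefore validate the pipeline's statistical machinery, not its
behaviour on pathological real-world scans.

## Six curves, smoothing and peak detection

Scans are aligned to a common 35–95 °C grid (0.1 °C step) by interpolating
cubic splines — exact at the original knots and on polynomials up to cubic —
with extrapolation refused. The ratio is formed from the raw resampled
channels; the three derivatives come from Savitzky–Golay
smoothing-differentiation (order 3).

* **Window 7 °C (default).** The SG first-derivative noise gain at a
  1.5 °C/0.1 °C window is 1.52, which puts spurious derivative wiggles from
  0.2% channel noise on the same footing as genuine transition peaks and
  jitters apex positions by 0.3–0.6 °C. A 7 °C window (about twice the
  transition FWHM) cuts the noise gain ~8-fold: spurious prominences fall
  far below real peaks, apex positions stabilise to ~0.1 °C, and — because
  the kernel is symmetric — noiseless apex positions are unbiased. Two
  transitions ≥ 6 °C apart remain resolved, which covers both mixture
  presets (gap ≈ 6.5 °C) and all patient-like profiles (gap ≥ 10 °C).
* **Edge handling.** Within half a window of each grid end the derivative
  comes from one-sided fits with several-fold higher variance. Peak
  candidates are therefore only accepted there as *boundary candidates*: a
  monotone run across the half-window into the edge, reported at the edge
  temperature and flagged censored. This is how the Fe³⁺-loaded LTF scan
  reports its 95.0 °C apex at the scan limit.
* **Detection.** Candidates need topographic prominence ≥ 5% of the
  derivative's range; if more than two survive, the two most prominent are
  kept and ordered into (T1m, T2m). A lone peak is assigned to T2m if its
  apex is ≥ 71 °C (the midpoint between the typical peak positions) else to
  T1m. Interior apexes are refined by a three-point quadratic fit and
  reported to 0.1 °C. A flat derivative returns an empty pair rather than an
  error.

## Clustering and classification

**k-means (k = 2)** runs Lloyd's algorithm on raw °C coordinates — both axes
are temperatures on the same scale, so no standardization by default (a
`standardize` switch exists). Each of 50 restarts initialises the centres at
two distinct points drawn from the sorted unique points (making the result
invariant to input row order), an emptied cluster is reseeded to the farthest
point, and the best-inertia restart wins, deterministically per seed. The
POAG-like cluster is defined as the lower-T1m centre. On two-Gaussian cohorts
with centre separation ≥ 6 within-class SDs the partition matches exhaustive
enumeration and recovers truth with adjusted Rand ≥ 0.95.

**Classification** uses the whole profile: the six curves sampled every
0.5 °C give 121 × 6 = 726 features per subject, in fixed block order (F330,
F350, ratio, dF330, dF350, dratio). The four learners carry fixed
hyperparameters: ridge-penalised logistic regression at the C = 1 convention
(λ = 1/n, warm-started coordinate-descent path), SVM with polynomial kernel
of degree 1, cost 1, kernel scale 1/p; random forest with 500 trees;
AdaBoost.M1 with 100 rounds over depth-3 CART trees (implemented in-package
over `rpart`, with weighted refits and learner weights
$\alpha = \tfrac12\log\frac{1-\epsilon}{\epsilon}$). Evaluation is stratified
5-fold cross-validation, shuffled once per seed, with per-feature z-scoring
fitted on each training fold only (no leakage). The summary reports the mean
fold accuracy with a normal-approximation 95% CI half-width,
$1.96\,\mathrm{SD}/\sqrt{5}$, and the pooled out-of-fold confusion table
(positive class = POAG), from which sensitivity and false-positive rate are
derived.

A note on the permutation null: the mean 5-fold CV accuracy under permuted
labels is centred at 50% but *overdispersed* relative to a binomial count of
n independent predictions, because training folds overlap (we measured
inflation factors of 1.2–1.45 for all four learners, and reproduced the same
inflation with an independent scikit-learn logistic regression on exported
features). The regression tests therefore check that each learner's null
accuracy is at chance **on average** across 20 seeded permutations — a
statistic with ~9σ of margin against any leakage — rather than asserting a
per-repetition binomial band that even a correct implementation would fail a
substantial fraction of the time.

## Numerical conventions and degenerate inputs

* Temperatures are °C externally, converted with the 273.15 offset
  internally; R = 8.314462618 J mol⁻¹ K⁻¹.
* Peak temperatures are reported to 0.1 °C, matching the assay's convention.
* Seeds: every stochastic step takes an explicit integer seed and restores
  the caller's RNG state; derived child seeds stay below 2³¹.
* Degenerate cases: flat derivative → empty peak pair; a zero-amplitude
  profile spec → warning plus flat profile; all-identical clustering input →
  error; empty mixture → error; a class missing from a training fold →
  error.

## Problem sizes used by the tests and the acceptance script

Single-scan checks run on the full 601-point grid. The cohort-level checks
use 100 + 100 subjects (clustering) and 25 + 25 subjects at 1 °C feature
spacing (classifier calibration); the permutation-repeat regression uses
25 + 25 subjects at 2 °C spacing. These sizes give Monte-Carlo error
comfortably inside the stated tolerances (e.g. ±0.3 °C for recovered cluster
centres) while keeping the whole suite in the minutes range.

## Known limitations

* The mechanistic model cannot place mixture peaks outside the span of its
  component Tms (no protein–protein interaction terms, no ΔCp curvature, no
  aggregation channel); quantities that depend on those effects are handled
  only through the phenomenological generator.
* One shared ΔH and emission model for all species is a simplification; both
  are configurable per species.
* The classifier benchmark validates calibration (separable → high accuracy,
  null → chance, reproducible), not clinical performance: the real patient
  scans behind the published accuracies are not redistributable, and no
  claim about them is made here.
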