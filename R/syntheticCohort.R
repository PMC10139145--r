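#' TwoPeakSpec: phenomenological two-transition profile shape
#'
#' Shape parameters of a patient-like denaturation profile whose
#' fluorescence ratio is a baseline plus two logistic steps: the ratio
#' derivative then has local maxima at the two step midpoints (t1m, t2m).
#' This generator controls peak positions directly, which the mechanistic
#' mixture model cannot (mixture peaks there are bounded by component Tms),
#' so cohort-level clustering and classification can be tested against
#' known truth.
#'
#' @slot t1m,t2m transition midpoints, degrees C; t1m < t2m when both steps
#'   have positive amplitude.
#' @slot width1,width2 logistic scales, degrees C, > 0.
#' @slot amp1,amp2 ratio-step amplitudes, dimensionless >= 0.
#' @slot ratioBaseline,ratioSlope ratio level at 35 degrees C and linear
#'   drift per degree C.
#' @slot f330Level,f330Decay F330 level (RFU, > 0) at 35 degrees C and
#'   fractional decay per degree C.
#' @slot noiseSigmaRel relative noise SD.
#' @exportClass TwoPeakSpec
setClass("TwoPeakSpec",
  representation(t1m = "numeric", t2m = "numeric",
                 width1 = "numeric", width2 = "numeric",
                 amp1 = "numeric", amp2 = "numeric",
                 ratioBaseline = "numeric", ratioSlope = "numeric",
                 f330Level = "numeric", f330Decay = "numeric",
                 noiseSigmaRel = "numeric"))

setValidity("TwoPeakSpec", function(object) {
  msg <- character()
  if (object@width1 <= 0 || object@width2 <= 0)
    msg <- c(msg, "widths must be > 0")
  if (object@amp1 < 0 || object@amp2 < 0)
    msg <- c(msg, "amplitudes must be >= 0")
  if (object@amp1 > 0 && object@amp2 > 0 && !(object@t1m < object@t2m))
    msg <- c(msg, "t1m must be < t2m when both amplitudes are positive")
  if (object@f330Level <= 0) msg <- c(msg, "f330Level must be > 0")
  if (object@noiseSigmaRel < 0) msg <- c(msg, "noiseSigmaRel must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a TwoPeakSpec
#'
#' Defaults give a tear-like profile: ratio near 0.85 rising by 0.18 and
#' 0.24 through the two transitions (patient ratio curves climb from
#' roughly 0.8 to well above 1 over the scan, the second transition being
#' the larger), logistic scale 0.9 degrees C (derivative FWHM about 3.2
#' degrees C, a sharp cooperative transition), F330 around 2000 RFU with
#' mild thermal quenching, and 0.2% multiplicative noise. The step
#' amplitudes are set well clear of the instrument-level noise so that, as
#' in patient scans, both apexes are reliably detectable.
#'
#' @param t1m,t2m transition midpoints, degrees C.
#' @param width1,width2 logistic scales, degrees C.
#' @param amp1,amp2 ratio-step amplitudes.
#' @param ratioBaseline,ratioSlope ratio level and drift.
#' @param f330Level,f330Decay F330 level and fractional decay.
#' @param noiseSigmaRel relative noise SD.
#' @return A [TwoPeakSpec-class].
#' @export
TwoPeakSpec <- function(t1m, t2m, width1 = 0.9, width2 = 0.9,
                        amp1 = 0.18, amp2 = 0.24,
                        ratioBaseline = 0.85, ratioSlope = 0.001,
                        f330Level = 2000, f330Decay = 0.002,
                        noiseSigmaRel = 0.002) {
  new("TwoPeakSpec", t1m = t1m, t2m = t2m, width1 = width1, width2 = width2,
      amp1 = amp1, amp2 = amp2, ratioBaseline = ratioBaseline,
      ratioSlope = ratioSlope, f330Level = f330Level, f330Decay = f330Decay,
      noiseSigmaRel = noiseSigmaRel)
}

setMethod("show", "TwoPeakSpec", function(object) {
  cat(sprintf("TwoPeakSpec: t1m %.1f, t2m %.1f degC (widths %.2f/%.2f)\n",
              object@t1m, object@t2m, object@width1, object@width2))
})

#' Generate one patient-like melting scan
#'
#' The ratio curve is `baseline + slope (T - 35) + amp1 L((T - t1m)/width1)
#' + amp2 L((T - t2m)/width2)` with L the logistic CDF; F330 decays
#' linearly, and F350 = ratio * F330. Multiplicative seeded Gaussian noise
#' is applied to both channels. When the transitions are well separated
#' (|t2m - t1m| at least 6 times the larger width) the noiseless ratio
#' derivative peaks within 0.05 degrees C of each midpoint. A spec with both
#' amplitudes zero is degenerate: a warning is raised and the flat profile
#' returned.
#'
#' @param spec a [TwoPeakSpec-class].
#' @param grid a [TemperatureGrid-class].
#' @param seed integer RNG seed for the noise draw.
#' @param sampleId,label identifier and class label for the run.
#' @return A [NanoDSFRun-class].
#' @examples
#' run <- generateProfile(TwoPeakSpec(64.6, 79.3, noiseSigmaRel = 0))
#' peakTemps(detectPeaks(sixCurves(run)))
#' @export
setGeneric("generateProfile",
  function(spec, grid = TemperatureGrid(), seed = 1L,
           sampleId = "synthetic", label = NA_character_)
    standardGeneric("generateProfile"))

#' @rdname generateProfile
setMethod("generateProfile", "TwoPeakSpec",
  function(spec, grid, seed, sampleId, label) {
    if (spec@amp1 == 0 && spec@amp2 == 0)
      warning("degenerate TwoPeakSpec: both amplitudes are zero; ",
              "returning a flat profile")
    tt <- gridTemps(grid)
    ratio <- spec@ratioBaseline + spec@ratioSlope * (tt - 35) +
      spec@amp1 * stats::plogis((tt - spec@t1m) / spec@width1) +
      spec@amp2 * stats::plogis((tt - spec@t2m) / spec@width2)
    f330 <- spec@f330Level * (1 - spec@f330Decay * (tt - 35))
    f350 <- ratio * f330
    if (spec@noiseSigmaRel > 0) {
      noisy <- .withSeed(seed, list(
        f330 = f330 * (1 + spec@noiseSigmaRel * stats::rnorm(length(tt))),
        f350 = f350 * (1 + spec@noiseSigmaRel * stats::rnorm(length(tt)))))
      f330 <- noisy$f330
      f350 <- noisy$f350
    }
    NanoDSFRun(sampleId, tt, f330, f350, label = label,
               meta = list(true_t1m = spec@t1m, true_t2m = spec@t2m,
                           seed = seed))
  })

#' CohortConfig: study design of a synthetic two-class cohort
#'
#' Class-conditional Gaussian means and SDs of the (T1m, T2m) biomarker for
#' a CONTROL-like and a POAG-like class, plus per-subject shape jitter. The
#' default class means are the two cluster averages observed in patient
#' tears -- (67.9, 77.7) degrees C for the control-like and (64.6, 79.3)
#' degrees C for the glaucoma-like population; within-class SDs default to
#' 0.8 degrees C (a stand-in: within-cluster spreads are not published).
#'
#' @slot meanT1m,meanT2m named numeric `c(CONTROL=, POAG=)`, degrees C.
#' @slot sdT1m,sdT2m named numeric SDs, degrees C, >= 0.
#' @slot n named integer subjects per class, each >= 2.
#' @slot jitter named numeric SDs of shape-parameter jitter
#'   (width, amp, baseline, level as a log-normal sigma).
#' @slot noiseSigmaRel relative measurement noise applied to every run.
#' @slot seed integer master seed; per-subject child seeds are derived with
#'   a fixed integer mix so cohorts reproduce across platforms.
#' @exportClass CohortConfig
setClass("CohortConfig",
  representation(meanT1m = "numeric", meanT2m = "numeric",
                 sdT1m = "numeric", sdT2m = "numeric", n = "integer",
                 jitter = "numeric", noiseSigmaRel = "numeric",
                 seed = "integer"))

setValidity("CohortConfig", function(object) {
  msg <- character()
  cls <- c("CONTROL", "POAG")
  for (s in c("meanT1m", "meanT2m", "sdT1m", "sdT2m", "n"))
    if (!identical(names(slot(object, s)), cls))
      msg <- c(msg, paste0(s, " must be named c(CONTROL=, POAG=)"))
  if (!length(msg)) {
    if (any(object@n < 2L)) msg <- c(msg, "need n >= 2 per class")
    if (any(c(object@sdT1m, object@sdT2m) < 0)) msg <- c(msg, "SDs must be >= 0")
    if (any(object@meanT1m >= object@meanT2m - 4))
      msg <- c(msg, "mean_t1m must be below mean_t2m - 4 degC in both classes")
    if (object@noiseSigmaRel < 0) msg <- c(msg, "noiseSigmaRel must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortConfig
#'
#' @param meanT1m,meanT2m class means, degrees C (named CONTROL/POAG).
#' @param sdT1m,sdT2m class SDs, degrees C.
#' @param n subjects per class.
#' @param jitter shape-jitter SDs: `width` and `amp` additive (degrees C /
#'   dimensionless), `baseline` additive, `logLevel` log-normal sigma of the
#'   F330 level.
#' @param noiseSigmaRel per-run relative noise SD.
#' @param seed master RNG seed.
#' @return A [CohortConfig-class].
#' @export
CohortConfig <- function(meanT1m = c(CONTROL = 67.9, POAG = 64.6),
                         meanT2m = c(CONTROL = 77.7, POAG = 79.3),
                         sdT1m = c(CONTROL = 0.8, POAG = 0.8),
                         sdT2m = c(CONTROL = 0.8, POAG = 0.8),
                         n = c(CONTROL = 100L, POAG = 100L),
                         jitter = c(width = 0.1, amp = 0.02,
                                    baseline = 0.02, logLevel = 0.1),
                         noiseSigmaRel = 0.002, seed = 1L) {
  new("CohortConfig", meanT1m = meanT1m, meanT2m = meanT2m, sdT1m = sdT1m,
      sdT2m = sdT2m, n = stats::setNames(as.integer(n), names(n)),
      jitter = jitter,
      noiseSigmaRel = noiseSigmaRel, seed = as.integer(seed))
}

#' CohortDataset: labelled synthetic cohort with generation truth
#'
#' @slot runs list of [NanoDSFRun-class].
#' @slot labels factor with levels CONTROL, POAG, one per run.
#' @slot truth data.frame (sample_id, label, true_t1m, true_t2m).
#' @exportClass CohortDataset
setClass("CohortDataset",
  representation(runs = "list", labels = "factor", truth = "data.frame"))

setValidity("CohortDataset", function(object) {
  msg <- character()
  if (length(object@runs) != length(object@labels) ||
      nrow(object@truth) != length(object@runs))
    msg <- c(msg, "runs, labels and truth must have equal length")
  if (!identical(levels(object@labels), c("CONTROL", "POAG")))
    msg <- c(msg, "labels must be a factor with levels CONTROL, POAG")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CohortDataset", function(object) {
  cat(sprintf("CohortDataset: %d runs (%s)\n", length(object@runs),
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels, 2)), collapse = ", ")))
})

#' Cohort accessors
#'
#' @param x a [CohortDataset-class].
#' @return `cohortRuns()` the list of runs; `cohortLabels()` the label
#'   factor; `cohortTruth()` the per-subject true peak positions.
#' @export
cohortRuns <- function(x) { stopifnot(is(x, "CohortDataset")); x@runs }

#' @rdname cohortRuns
#' @export
cohortLabels <- function(x) { stopifnot(is(x, "CohortDataset")); x@labels }

#' @rdname cohortRuns
#' @export
cohortTruth <- function(x) { stopifnot(is(x, "CohortDataset")); x@truth }

#' Generate a labelled two-class cohort of melting scans
#'
#' For each subject, true (t1m, t2m) are drawn from the class-conditional
#' Gaussians (rejection-resampled until t1m < t2m - 4 degrees C), the
#' profile shape parameters are jittered, and a scan is generated with
#' [generateProfile()] under a per-subject child seed derived
#' deterministically from the master seed. Class labels are CONTROL = 0 and
#' POAG = 1 in downstream classification.
#'
#' @param config a [CohortConfig-class].
#' @param grid a [TemperatureGrid-class].
#' @return A [CohortDataset-class].
#' @examples
#' ds <- generateCohort(CohortConfig(n = c(CONTROL = 5L, POAG = 5L)))
#' ds
#' @export
generateCohort <- function(config, grid = TemperatureGrid()) {
  validObject(config)
  runs <- list()
  labels <- character(0)
  truth <- list()
  k <- 0L
  for (cls in c("CONTROL", "POAG")) {
    for (i in seq_len(config@n[[cls]])) {
      k <- k + 1L
      childSeed <- .childSeed(config@seed, k)
      par <- .withSeed(childSeed, {
        repeat {
          t1 <- stats::rnorm(1, config@meanT1m[[cls]], config@sdT1m[[cls]])
          t2 <- stats::rnorm(1, config@meanT2m[[cls]], config@sdT2m[[cls]])
          if (t1 < t2 - 4) break
        }
        list(t1 = t1, t2 = t2,
             w1 = max(0.5, 0.9 + stats::rnorm(1, 0, config@jitter[["width"]])),
             w2 = max(0.5, 0.9 + stats::rnorm(1, 0, config@jitter[["width"]])),
             a1 = max(0.05, 0.18 + stats::rnorm(1, 0, config@jitter[["amp"]])),
             a2 = max(0.05, 0.24 + stats::rnorm(1, 0, config@jitter[["amp"]])),
             b  = 0.85 + stats::rnorm(1, 0, config@jitter[["baseline"]]),
             lv = 2000 * exp(stats::rnorm(1, 0, config@jitter[["logLevel"]])))
      })
      spec <- TwoPeakSpec(par$t1, par$t2, width1 = par$w1, width2 = par$w2,
                          amp1 = par$a1, amp2 = par$a2, ratioBaseline = par$b,
                          f330Level = par$lv,
                          noiseSigmaRel = config@noiseSigmaRel)
      id <- sprintf("S%03d_%s", k, cls)
      runs[[k]] <- generateProfile(spec, grid, seed = .childSeed(childSeed, 1L),
                                   sampleId = id, label = cls)
      labels[k] <- cls
      truth[[k]] <- data.frame(sample_id = id, label = cls,
                               true_t1m = par$t1, true_t2m = par$t2)
    }
  }
  new("CohortDataset", runs = runs,
      labels = factor(labels, levels = c("CONTROL", "POAG")),
      truth = do.call(rbind, truth))
}

#' Write a cohort to CSV
#'
#' Writes the long-format scan CSV (see [writeRuns()]) and a truth sidecar
#' CSV (sample_id, label, true_t1m, true_t2m).
#'
#' @param dataset a [CohortDataset-class].
#' @param path scan CSV path; the sidecar gets suffix `_truth.csv`.
#' @return Invisibly, c(scans = path, truth = sidecarPath).
#' @export
writeCohort <- function(dataset, path) {
  writeRuns(dataset@runs, path)
  sidecar <- sub("\\.csv$", "", path)
  sidecar <- paste0(sidecar, "_truth.csv")
  utils::write.csv(dataset@truth, sidecar, row.names = FALSE)
  invisible(c(scans = path, truth = sidecar))
}
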