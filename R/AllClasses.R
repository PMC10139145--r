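#' @import methods
NULL

## Internal: gas constant, kJ mol^-1 K^-1
.R_GAS <- 0.008314462618
.KELVIN <- 273.15

#' TemperatureGrid: a regular temperature ramp
#'
#' A regular scan grid in degrees Celsius, the common axis onto which melting
#' scans are resampled. The default mirrors the instrument ramp used for tear
#' samples: 35 to 95 degrees C.
#'
#' @slot start numeric(1), first temperature (degrees C).
#' @slot stop numeric(1), last temperature (degrees C).
#' @slot step numeric(1), grid spacing (degrees C), > 0.
#' @exportClass TemperatureGrid
setClass("TemperatureGrid",
  representation(start = "numeric", stop = "numeric", step = "numeric"),
  prototype(start = 35, stop = 95, step = 0.1))

setValidity("TemperatureGrid", function(object) {
  msg <- character()
  if (!all(is.finite(c(object@start, object@stop, object@step))))
    msg <- c(msg, "start, stop and step must be finite")
  else {
    if (object@step <= 0) msg <- c(msg, "step must be > 0")
    if (object@stop <= object@start) msg <- c(msg, "stop must exceed start")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TemperatureGrid
#'
#' @param start,stop,step grid limits and spacing in degrees C. Defaults give
#'   the standard 35-95 degrees C scan at 0.1 degrees C resolution.
#' @return A [TemperatureGrid-class] object.
#' @examples
#' gridTemps(TemperatureGrid())[1:5]
#' @export
TemperatureGrid <- function(start = 35, stop = 95, step = 0.1) {
  new("TemperatureGrid", start = start, stop = stop, step = step)
}

#' Grid temperatures as a numeric vector
#'
#' @param grid a [TemperatureGrid-class].
#' @return Numeric vector of temperatures (degrees C).
#' @export
gridTemps <- function(grid) {
  stopifnot(is(grid, "TemperatureGrid"))
  seq(grid@start, grid@stop, by = grid@step)
}

#' ProteinSpecies: thermodynamic and emission parameters of one protein
#'
#' Two-state unfolder parameterised by its melting temperature and van't Hoff
#' enthalpy, plus per-wavelength emission coefficients: mean signal per unit
#' concentration (a330, a350, RFU per ug/mL), folded-to-unfolded contrast
#' (d330, d350, RFU per ug/mL) and linear baseline drift (fraction per
#' degree C). Unfolding red-shifts intrinsic fluorescence, so d350 > 0 and
#' d330 < 0; the contrast is capped at 5% of the mean signal. The ratio
#' F350/F330 is a Moebius function of the fraction unfolded, whose
#' derivative apex sits above Tm by about 2 (d/a) s with s = R Tm^2 / dH
#' the transition scale; the cap (and the 1% default contrast) keeps that
#' bias well below the 0.1 degrees C reporting precision.
#'
#' @slot name character identifier (e.g. "HSA").
#' @slot tm numeric, melting temperature, degrees C.
#' @slot dh numeric, van't Hoff enthalpy, kJ/mol, > 0.
#' @slot a330,a350 numeric, mean emission per unit concentration.
#' @slot d330,d350 numeric, unfolding contrast per unit concentration.
#' @slot slope330,slope350 numeric, baseline drift, fraction per degree C.
#' @exportClass ProteinSpecies
setClass("ProteinSpecies",
  representation(name = "character", tm = "numeric", dh = "numeric",
    a330 = "numeric", a350 = "numeric",
    d330 = "numeric", d350 = "numeric",
    slope330 = "numeric", slope350 = "numeric"))

setValidity("ProteinSpecies", function(object) {
  msg <- character()
  num <- c(object@tm, object@dh, object@a330, object@a350, object@d330,
           object@d350, object@slope330, object@slope350)
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(num) != 8L || !all(is.finite(num)))
    msg <- c(msg, "all numeric parameters must be finite scalars")
  else {
    if (object@dh <= 0) msg <- c(msg, "dh (van't Hoff enthalpy) must be > 0")
    if (object@tm < 20 || object@tm > 110)
      msg <- c(msg, "tm must lie in [20, 110] degrees C")
    if (object@a330 <= 0 || object@a350 <= 0)
      msg <- c(msg, "mean emission coefficients must be > 0")
    if (abs(object@d330) / object@a330 > 0.05 ||
        abs(object@d350) / object@a350 > 0.05)
      msg <- c(msg, "|d|/a must be <= 0.05 at both wavelengths")
    if (!(object@d350 > 0 && object@d330 < 0))
      msg <- c(msg, "contrast signs must satisfy d350 > 0 and d330 < 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ProteinSpecies
#'
#' @param name identifier.
#' @param tm melting temperature, degrees C.
#' @param dh van't Hoff enthalpy, kJ/mol. The default 800 kJ/mol gives a
#'   derivative-peak width (FWHM about 4-5 degrees C) typical of cooperative
#'   unfolding near 340 K, sharp enough that the low-Tm (67.4-69.4 degrees C)
#'   and high-Tm (72.9-75.1 degrees C) groups of the core tear proteins
#'   resolve into two distinct peaks in mixture scans.
#' @param a330,a350 mean emission per ug/mL (RFU).
#' @param d330,d350 folded-to-unfolded emission contrast per ug/mL; defaults
#'   -0.01/+0.01 (1% of the mean, deep in the low-contrast regime where the
#'   ratio-derivative apex coincides with Tm to reporting precision).
#' @param slope330,slope350 linear baseline drift, fraction per degree C.
#' @return A [ProteinSpecies-class].
#' @examples
#' hsa <- ProteinSpecies("HSA", tm = 75.1)
#' fractionUnfolded(hsa, 75.1)
#' @export
ProteinSpecies <- function(name, tm, dh = 800,
                           a330 = 1, a350 = 1, d330 = -0.01, d350 = 0.01,
                           slope330 = 0, slope350 = 0) {
  new("ProteinSpecies", name = name, tm = tm, dh = dh, a330 = a330,
      a350 = a350, d330 = d330, d350 = d350,
      slope330 = slope330, slope350 = slope350)
}

setMethod("show", "ProteinSpecies", function(object) {
  cat(sprintf("ProteinSpecies %s: Tm = %.1f degC, dHvH = %g kJ/mol\n",
              object@name, object@tm, object@dh))
})

#' LigandModifier: ligand-induced Tm shifts
#'
#' A bound ligand (fatty acid, metal ion, drug) modelled as saturating:
#' every affected species carries its shifted melting temperature, either as
#' an absolute replacement Tm or as a delta. Species absent from the shift
#' table are unaffected.
#'
#' @slot ligand character identifier (e.g. "MYRISTATE").
#' @slot shifts named list; each element is `list(tm = <abs degC>)` or
#'   `list(dtm = <delta degC>)`, named by species.
#' @exportClass LigandModifier
setClass("LigandModifier",
  representation(ligand = "character", shifts = "list"))

setValidity("LigandModifier", function(object) {
  msg <- character()
  if (length(object@ligand) != 1L || !nzchar(object@ligand))
    msg <- c(msg, "ligand must be a non-empty string")
  if (length(object@shifts)) {
    if (is.null(names(object@shifts)) || any(!nzchar(names(object@shifts))))
      msg <- c(msg, "shifts must be named by species")
    ok <- vapply(object@shifts, function(s) {
      is.list(s) && length(s) == 1L && names(s) %in% c("tm", "dtm") &&
        is.numeric(s[[1]]) && is.finite(s[[1]])
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "each shift must be list(tm=) or list(dtm=) with a finite value")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a LigandModifier
#'
#' @param ligand identifier.
#' @param shifts named list of per-species shifts, each `list(tm=)` (absolute
#'   replacement) or `list(dtm=)` (additive). An empty list is a no-op ligand.
#' @return A [LigandModifier-class].
#' @examples
#' LigandModifier("MYRISTATE", list(HSA = list(tm = 80.3), LYZ = list(tm = 55.6)))
#' @export
LigandModifier <- function(ligand, shifts = list()) {
  new("LigandModifier", ligand = ligand, shifts = shifts)
}

setMethod("show", "LigandModifier", function(object) {
  cat(sprintf("LigandModifier %s (%d species affected)\n",
              object@ligand, length(object@shifts)))
})

#' MixtureSpec: a named mixture of proteins with ligand state
#'
#' @slot name label.
#' @slot species list of [ProteinSpecies-class].
#' @slot concentrations numeric, ug/mL, aligned with species.
#' @slot ligands list of [LigandModifier-class] (not yet applied; see
#'   [applyLigands()]).
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(name = "character", species = "list",
                 concentrations = "numeric", ligands = "list"))

setValidity("MixtureSpec", function(object) {
  msg <- character()
  if (length(object@species) != length(object@concentrations))
    msg <- c(msg, "species and concentrations must have equal length")
  if (!all(vapply(object@species, is, logical(1), "ProteinSpecies")))
    msg <- c(msg, "species must all be ProteinSpecies")
  if (!all(is.finite(object@concentrations)) || any(object@concentrations < 0))
    msg <- c(msg, "concentrations must be finite and >= 0")
  if (!any(object@concentrations > 0))
    msg <- c(msg, "at least one component must have concentration > 0")
  if (!all(vapply(object@ligands, is, logical(1), "LigandModifier")))
    msg <- c(msg, "ligands must all be LigandModifier")
  if (length(msg)) msg else TRUE
})

#' Construct a MixtureSpec
#'
#' @param species a [ProteinSpecies-class] or list of them.
#' @param concentrations numeric vector, ug/mL.
#' @param ligands list of [LigandModifier-class].
#' @param name label for the mixture.
#' @return A [MixtureSpec-class].
#' @export
MixtureSpec <- function(species, concentrations, ligands = list(),
                        name = "mixture") {
  if (is(species, "ProteinSpecies")) species <- list(species)
  new("MixtureSpec", name = name, species = species,
      concentrations = as.numeric(concentrations), ligands = ligands)
}

setMethod("show", "MixtureSpec", function(object) {
  cat(sprintf("MixtureSpec '%s': %d component(s)\n", object@name,
              length(object@species)))
  for (i in seq_along(object@species))
    cat(sprintf("  %-6s %6.1f ug/mL  Tm %.1f degC\n",
                object@species[[i]]@name, object@concentrations[i],
                object@species[[i]]@tm))
  if (length(object@ligands))
    cat("  ligands:", paste(vapply(object@ligands, slot, "", "ligand"),
                            collapse = ", "), "\n")
})

#' NanoDSFRun: one melting scan
#'
#' A single thermal scan: an ascending temperature series and the intrinsic
#' fluorescence recorded at 330 and 350 nm, with sample metadata.
#'
#' @slot sampleId character identifier.
#' @slot label character class label ("CONTROL", "POAG", ...) or NA.
#' @slot meta list of free-form metadata.
#' @slot temperatures numeric, degrees C, strictly increasing, length >= 16.
#' @slot f330,f350 numeric, RFU, finite and > 0.
#' @exportClass NanoDSFRun
setClass("NanoDSFRun",
  representation(sampleId = "character", label = "character", meta = "list",
                 temperatures = "numeric", f330 = "numeric", f350 = "numeric"))

setValidity("NanoDSFRun", function(object) {
  msg <- character()
  n <- length(object@temperatures)
  if (length(object@sampleId) != 1L) msg <- c(msg, "sampleId must be scalar")
  if (length(object@label) != 1L) msg <- c(msg, "label must be scalar (NA allowed)")
  if (n < 16L) msg <- c(msg, "scan must have at least 16 points")
  if (length(object@f330) != n || length(object@f350) != n)
    msg <- c(msg, "temperatures, f330 and f350 must have equal length")
  if (n && (!all(is.finite(object@temperatures)) ||
            any(diff(object@temperatures) <= 0)))
    msg <- c(msg, "temperatures must be finite and strictly increasing")
  if (!all(is.finite(object@f330)) || !all(is.finite(object@f350)) ||
      any(object@f330 <= 0) || any(object@f350 <= 0))
    msg <- c(msg, "intensities must be finite and > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a NanoDSFRun
#'
#' @param sampleId identifier.
#' @param temperatures ascending temperatures, degrees C.
#' @param f330,f350 fluorescence series, RFU.
#' @param label optional class label.
#' @param meta optional metadata list.
#' @return A [NanoDSFRun-class].
#' @export
NanoDSFRun <- function(sampleId, temperatures, f330, f350,
                       label = NA_character_, meta = list()) {
  new("NanoDSFRun", sampleId = as.character(sampleId),
      label = as.character(label), meta = meta,
      temperatures = as.numeric(temperatures),
      f330 = as.numeric(f330), f350 = as.numeric(f350))
}

setMethod("show", "NanoDSFRun", function(object) {
  cat(sprintf("NanoDSFRun %s [%s]: %d points, %.1f-%.1f degC\n",
              object@sampleId,
              ifelse(is.na(object@label), "unlabelled", object@label),
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures)))
})

#' @rdname accessors
#' @export
setGeneric("temperatures", function(x) standardGeneric("temperatures"))
#' @rdname accessors
#' @export
setGeneric("f330", function(x) standardGeneric("f330"))
#' @rdname accessors
#' @export
setGeneric("f350", function(x) standardGeneric("f350"))
#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setGeneric("runLabel", function(x) standardGeneric("runLabel"))

#' Accessors for scan and curve objects
#'
#' `temperatures()`, `f330()`, `f350()` return the temperature and channel
#' series of a [NanoDSFRun-class] or [SixCurveSet-class]; `sampleId()` and
#' `runLabel()` return a run's identifier and class label.
#'
#' @param x a [NanoDSFRun-class] or [SixCurveSet-class].
#' @return Numeric vector (or character for id/label).
#' @name accessors
NULL

#' @rdname accessors
setMethod("temperatures", "NanoDSFRun", function(x) x@temperatures)
#' @rdname accessors
setMethod("f330", "NanoDSFRun", function(x) x@f330)
#' @rdname accessors
setMethod("f350", "NanoDSFRun", function(x) x@f350)
#' @rdname accessors
setMethod("sampleId", "NanoDSFRun", function(x) x@sampleId)
#' @rdname accessors
setMethod("runLabel", "NanoDSFRun", function(x) x@label)

#' SixCurveSet: the six-curve denaturation profile
#'
#' The denaturation profile of one sample on a common grid: F330, F350, their
#' ratio F350/F330, and the first temperature derivatives of all three. The
#' ratio is formed from the raw resampled channels; derivatives come from
#' Savitzky-Golay smoothing-differentiation. Derivative values within half a
#' smoothing window of either grid end are computed with one-sided polynomial
#' fits; `edgePoints` records that half-window so boundary peaks can be
#' recognised downstream.
#'
#' @slot temperatures common grid, degrees C.
#' @slot f330,f350,ratio resampled channel series and pointwise ratio.
#' @slot dF330,dF350,dRatio first derivatives, units per degree C.
#' @slot edgePoints integer, half-window length (points) at each grid end.
#' @exportClass SixCurveSet
setClass("SixCurveSet",
  representation(temperatures = "numeric", f330 = "numeric", f350 = "numeric",
                 ratio = "numeric", dF330 = "numeric", dF350 = "numeric",
                 dRatio = "numeric", edgePoints = "integer"))

setValidity("SixCurveSet", function(object) {
  msg <- character()
  n <- length(object@temperatures)
  lens <- c(length(object@f330), length(object@f350), length(object@ratio),
            length(object@dF330), length(object@dF350), length(object@dRatio))
  if (!all(lens == n)) msg <- c(msg, "all six curves must match the grid length")
  else if (n > 0 &&
           max(abs(object@ratio - object@f350 / object@f330)) > 1e-8 * max(abs(object@ratio)))
    msg <- c(msg, "ratio must equal f350/f330 pointwise")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SixCurveSet", function(object) {
  cat(sprintf("SixCurveSet: %d points, %.1f-%.1f degC, ratio %.3f-%.3f\n",
              length(object@temperatures), min(object@temperatures),
              max(object@temperatures), min(object@ratio), max(object@ratio)))
})

#' @rdname accessors
setMethod("temperatures", "SixCurveSet", function(x) x@temperatures)
#' @rdname accessors
setMethod("f330", "SixCurveSet", function(x) x@f330)
#' @rdname accessors
setMethod("f350", "SixCurveSet", function(x) x@f350)

#' Ratio and derivative accessors
#'
#' @param x a [SixCurveSet-class].
#' @return Numeric vector on the set's grid.
#' @export
ratioCurve <- function(x) { stopifnot(is(x, "SixCurveSet")); x@ratio }

#' @rdname ratioCurve
#' @export
dRatioCurve <- function(x) { stopifnot(is(x, "SixCurveSet")); x@dRatio }

#' PeakPair: the (T1m, T2m) two-peak biomarker
#'
#' Result of peak detection on the derivative of the fluorescence ratio.
#' Either peak may be absent (NA). A peak whose apex coincides with a grid
#' edge is reported at the edge temperature and flagged censored.
#'
#' @slot t1m,t2m apex temperatures, degrees C (NA if absent); t1m < t2m when
#'   both are present.
#' @slot prominence1,prominence2 peak prominences, derivative units (NA if
#'   the peak is absent).
#' @slot censored1,censored2 logical boundary-censoring flags.
#' @slot nRawPeaks integer, number of prominence-passing candidates before
#'   the two-peak selection.
#' @exportClass PeakPair
setClass("PeakPair",
  representation(t1m = "numeric", t2m = "numeric",
                 prominence1 = "numeric", prominence2 = "numeric",
                 censored1 = "logical", censored2 = "logical",
                 nRawPeaks = "integer"))

setValidity("PeakPair", function(object) {
  msg <- character()
  if (!is.na(object@t1m) && !is.na(object@t2m) && !(object@t1m < object@t2m))
    msg <- c(msg, "t1m must be < t2m when both peaks are present")
  proms <- c(object@prominence1, object@prominence2)
  if (any(!is.na(proms) & proms < 0)) msg <- c(msg, "prominences must be >= 0")
  if (object@nRawPeaks < 0L) msg <- c(msg, "nRawPeaks must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PeakPair", function(object) {
  fmt <- function(t, cen) {
    if (is.na(t)) "absent"
    else sprintf("%.1f degC%s", t, if (cen) " (censored)" else "")
  }
  cat(sprintf("PeakPair: T1m = %s, T2m = %s (%d raw candidate(s))\n",
              fmt(object@t1m, object@censored1),
              fmt(object@t2m, object@censored2), object@nRawPeaks))
})

#' Peak-pair accessors
#'
#' @param x a [PeakPair-class].
#' @return `peakTemps()` a named numeric `c(t1m=, t2m=)`; `peakCensored()` a
#'   named logical pair; `nRawPeaks()` an integer count.
#' @export
peakTemps <- function(x) {
  stopifnot(is(x, "PeakPair")); c(t1m = x@t1m, t2m = x@t2m)
}

#' @rdname peakTemps
#' @export
peakCensored <- function(x) {
  stopifnot(is(x, "PeakPair")); c(t1m = x@censored1, t2m = x@censored2)
}

#' @rdname peakTemps
#' @export
nRawPeaks <- function(x) { stopifnot(is(x, "PeakPair")); x@nRawPeaks }

#' ClusterResult: two-group k-means partition of (T1m, T2m)
#'
#' @slot centers 2 x 2 matrix (rows: clusters; columns t1m, t2m), degrees C.
#' @slot assignments integer cluster index (1 or 2) per sample.
#' @slot inertia within-cluster sum of squared distances, degrees C squared.
#' @slot nRestarts,seed restart count and RNG seed used.
#' @slot poagLikeCluster index (1 or 2) of the lower-T1m centre, the
#'   glaucoma-like population.
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(centers = "matrix", assignments = "integer",
                 inertia = "numeric", nRestarts = "integer", seed = "integer",
                 poagLikeCluster = "integer"))

setValidity("ClusterResult", function(object) {
  msg <- character()
  if (!all(dim(object@centers) == c(2L, 2L)))
    msg <- c(msg, "centers must be a 2 x 2 matrix")
  if (!all(object@assignments %in% c(1L, 2L)))
    msg <- c(msg, "assignments must be 1 or 2")
  if (object@inertia < 0) msg <- c(msg, "inertia must be >= 0")
  if (!object@poagLikeCluster %in% c(1L, 2L))
    msg <- c(msg, "poagLikeCluster must be 1 or 2")
  else if (nrow(object@centers) == 2L &&
           object@poagLikeCluster != which.min(object@centers[, 1]))
    msg <- c(msg, "poagLikeCluster must be the centre with the lower t1m")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat("ClusterResult (k = 2)\n")
  for (k in 1:2)
    cat(sprintf("  cluster %d: centre (%.2f, %.2f) degC, n = %d%s\n", k,
                object@centers[k, 1], object@centers[k, 2],
                sum(object@assignments == k),
                if (k == object@poagLikeCluster) "  <- POAG-like" else ""))
  cat(sprintf("  inertia %.3f (best of %d restarts, seed %d)\n",
              object@inertia, object@nRestarts, object@seed))
})

#' Cluster-result accessors
#'
#' @param x a [ClusterResult-class].
#' @return `clusterCenters()` the 2 x 2 centre matrix; `clusterAssignments()`
#'   the integer assignment vector; `poagLikeCluster()` the index of the
#'   lower-T1m (glaucoma-like) centre.
#' @export
clusterCenters <- function(x) { stopifnot(is(x, "ClusterResult")); x@centers }

#' @rdname clusterCenters
#' @export
clusterAssignments <- function(x) {
  stopifnot(is(x, "ClusterResult")); x@assignments
}

#' @rdname clusterCenters
#' @export
poagLikeCluster <- function(x) {
  stopifnot(is(x, "ClusterResult")); x@poagLikeCluster
}

#' EvaluationReport: cross-validated classifier benchmark
#'
#' Per-algorithm fold accuracies with a normal-approximation 95% confidence
#' interval of the mean, plus the pooled out-of-fold confusion table
#' (positive class = POAG).
#'
#' @slot folds data.frame (algorithm, fold, accuracy in percent).
#' @slot summary data.frame (algorithm, meanAccuracy, ciHalfwidth, percent).
#' @slot confusion named list per algorithm: integer c(TP, FP, TN, FN).
#' @slot featureDesc character, description of the feature grid.
#' @slot seed integer RNG seed; @slot nPerClass named integer class sizes.
#' @exportClass EvaluationReport
setClass("EvaluationReport",
  representation(folds = "data.frame", summary = "data.frame",
                 confusion = "list", featureDesc = "character",
                 seed = "integer", nPerClass = "integer"))

setValidity("EvaluationReport", function(object) {
  msg <- character()
  if (nrow(object@summary) &&
      (any(object@summary$meanAccuracy < 0) ||
       any(object@summary$meanAccuracy > 100)))
    msg <- c(msg, "mean accuracies must lie in [0, 100]")
  n <- sum(object@nPerClass)
  bad <- vapply(object@confusion, function(cm) sum(cm) != n, logical(1))
  if (any(bad)) msg <- c(msg, "confusion counts must sum to the sample size")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport: %d samples (%s), seed %d\n",
              sum(object@nPerClass),
              paste(sprintf("%s=%d", names(object@nPerClass),
                            object@nPerClass), collapse = ", "),
              object@seed))
  cat(sprintf("  features: %s\n", object@featureDesc))
  for (i in seq_len(nrow(object@summary))) {
    s <- object@summary[i, ]
    cm <- object@confusion[[s$algorithm]]
    cat(sprintf("  %-8s accuracy %.1f +/- %.1f %%   TP %d FP %d TN %d FN %d\n",
                s$algorithm, s$meanAccuracy, s$ciHalfwidth,
                cm["TP"], cm["FP"], cm["TN"], cm["FN"]))
  }
})

#' Evaluation-report accessors
#'
#' @param x an [EvaluationReport-class].
#' @return `foldAccuracies()` the long fold-level data.frame;
#'   `accuracySummary()` the per-algorithm mean and CI half-width (percent);
#'   `pooledConfusion()` the named list of confusion count vectors.
#' @export
foldAccuracies <- function(x) { stopifnot(is(x, "EvaluationReport")); x@folds }

#' @rdname foldAccuracies
#' @export
accuracySummary <- function(x) { stopifnot(is(x, "EvaluationReport")); x@summary }

#' @rdname foldAccuracies
#' @export
pooledConfusion <- function(x) { stopifnot(is(x, "EvaluationReport")); x@confusion }
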