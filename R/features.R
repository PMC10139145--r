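## Local maxima of y (interior strict-left, non-strict-right to break
## plateaus deterministically) plus boundary candidates. Interior candidates
## are restricted to the region where the derivative comes from centred
## Savitzky-Golay fits; within the one-sided half-window at each grid end
## only a monotone run into the edge qualifies, making the edge point a
## censored candidate.
.peakCandidates <- function(y, edge = 0L) {
  n <- length(y)
  idx <- integer(0)
  boundary <- logical(0)
  lo <- max(2L, edge + 1L)
  hi <- min(n - 1L, n - edge)
  if (hi >= lo) {
    mid <- lo:hi
    interior <- mid[y[mid] > y[mid - 1L] & y[mid] >= y[mid + 1L]]
    idx <- interior
    boundary <- rep(FALSE, length(interior))
  }
  k <- max(1L, edge)
  if (n > k) {
    if (all(diff(y[1:(k + 1L)]) <= 0) && y[1] > y[k + 1L]) {
      idx <- c(1L, idx); boundary <- c(TRUE, boundary)
    }
    if (all(diff(y[(n - k):n]) >= 0) && y[n] > y[n - k]) {
      idx <- c(idx, n); boundary <- c(boundary, TRUE)
    }
  }
  list(idx = idx, boundary = boundary)
}

## Topographic prominence: on each side, the minimum between the peak and
## the nearest higher point (or the signal edge); prominence is the peak
## height above the higher of the two side minima.
.peakProminence <- function(y, idx) {
  vapply(idx, function(i) {
    h <- y[i]
    left <- if (i > 1) {
      seg <- y[seq_len(i - 1)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[(max(higher)):(i - 1)]) else min(seg)
    } else -Inf                          # edge peak: only one flank counts
    right <- if (i < length(y)) {
      seg <- y[(i + 1):length(y)]
      higher <- which(seg > h)
      if (length(higher)) min(seg[1:(min(higher))]) else min(seg)
    } else -Inf
    h - max(left, right)
  }, numeric(1))
}

#' Extract the (T1m, T2m) biomarker from a six-curve profile
#'
#' Detects local maxima of the derivative of the fluorescence ratio,
#' `d(F350/F330)/dT`, and reduces them to the two-peak biomarker. Candidate
#' apexes are local maxima in the region covered by centred smoothing fits,
#' plus grid-edge points reached by a monotone run across the one-sided
#' half-window (boundary candidates, reported at the edge temperature and
#' flagged censored; the one-sided fits there are noisier, so isolated
#' wiggles in that margin never qualify). Candidates must have topographic prominence of at
#' least `minProminenceFrac` times the curve's global range. If more than
#' two candidates survive, the two most prominent are kept; the pair is then
#' ordered by temperature into (T1m, T2m). A single surviving peak is
#' assigned to T2m when its apex is at or above `splitTemp` and to T1m
#' otherwise. Interior apexes are refined by a 3-point quadratic fit and
#' reported to 0.1 degrees C; a flat derivative yields an empty pair rather
#' than an error.
#'
#' @param curves a [SixCurveSet-class].
#' @param minProminenceFrac prominence threshold as a fraction of the
#'   derivative's global range; default 0.05, in (0, 1).
#' @param splitTemp single-peak disambiguation temperature, degrees C;
#'   default 71 (midway between the typical T1m near 65 and T2m near 78).
#' @return A [PeakPair-class].
#' @examples
#' sc <- sixCurves(simulateScan(mixturePreset("CONTROL"), noiseSigmaRel = 0))
#' detectPeaks(sc)
#' @export
setGeneric("detectPeaks",
  function(curves, minProminenceFrac = 0.05, splitTemp = 71)
    standardGeneric("detectPeaks"))

#' @rdname detectPeaks
setMethod("detectPeaks", "SixCurveSet",
  function(curves, minProminenceFrac, splitTemp) {
    if (!(minProminenceFrac > 0 && minProminenceFrac < 1))
      stop("minProminenceFrac must be in (0, 1)")
    y <- curves@dRatio
    tt <- curves@temperatures
    empty <- new("PeakPair", t1m = NA_real_, t2m = NA_real_,
                 prominence1 = NA_real_, prominence2 = NA_real_,
                 censored1 = FALSE, censored2 = FALSE, nRawPeaks = 0L)
    rng <- max(y) - min(y)
    if (rng == 0) return(empty)
    cand <- .peakCandidates(y, curves@edgePoints)
    if (!length(cand$idx)) return(empty)
    prom <- .peakProminence(y, cand$idx)
    keep <- prom >= minProminenceFrac * rng
    idx <- cand$idx[keep]
    boundary <- cand$boundary[keep]
    prom <- prom[keep]
    nRaw <- length(idx)
    if (!nRaw) return(empty)
    if (nRaw > 2) {
      top <- order(prom, decreasing = TRUE)[1:2]
      idx <- idx[top]; boundary <- boundary[top]; prom <- prom[top]
    }
    apex <- function(i, bnd) {
      if (bnd || i == 1L || i == length(y)) return(tt[i])
      # 3-point quadratic refinement around the sampled apex
      d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
      tt[i] + d * (tt[2] - tt[1])
    }
    temps <- round(mapply(apex, idx, boundary), 1)
    ord <- order(temps)
    temps <- temps[ord]; boundary <- boundary[ord]; prom <- prom[ord]
    if (length(temps) == 1L) {
      if (temps >= splitTemp)
        new("PeakPair", t1m = NA_real_, t2m = temps,
            prominence1 = NA_real_, prominence2 = prom,
            censored1 = FALSE, censored2 = boundary, nRawPeaks = as.integer(nRaw))
      else
        new("PeakPair", t1m = temps, t2m = NA_real_,
            prominence1 = prom, prominence2 = NA_real_,
            censored1 = boundary, censored2 = FALSE, nRawPeaks = as.integer(nRaw))
    } else {
      new("PeakPair", t1m = temps[1], t2m = temps[2],
          prominence1 = prom[1], prominence2 = prom[2],
          censored1 = boundary[1], censored2 = boundary[2],
          nRawPeaks = as.integer(nRaw))
    }
  })

#' Peak extraction over a cohort of runs
#'
#' Runs every scan through the six-curve construction and peak detection and
#' tabulates the biomarker. Rows missing either peak are flagged incomplete
#' (they are excluded from clustering by default downstream).
#'
#' @param runs list of [NanoDSFRun-class] with unique sample ids.
#' @param grid common [TemperatureGrid-class].
#' @param window,polyorder Savitzky-Golay settings, see [sixCurves()].
#' @param minProminenceFrac,splitTemp peak settings, see [detectPeaks()].
#' @return data.frame with columns sample_id, label, t1m, t2m, prominence1,
#'   prominence2, censored1, censored2, complete.
#' @export
extractCohort <- function(runs, grid = TemperatureGrid(), window = 7,
                          polyorder = 3L, minProminenceFrac = 0.05,
                          splitTemp = 71) {
  if (!length(runs))
    return(data.frame(sample_id = character(), label = character(),
                      t1m = numeric(), t2m = numeric(),
                      prominence1 = numeric(), prominence2 = numeric(),
                      censored1 = logical(), censored2 = logical(),
                      complete = logical()))
  ids <- vapply(runs, sampleId, "")
  if (anyDuplicated(ids))
    stop("duplicate sample_id: ", ids[anyDuplicated(ids)])
  rows <- lapply(runs, function(r) {
    pp <- detectPeaks(sixCurves(r, grid, window, polyorder),
                      minProminenceFrac, splitTemp)
    data.frame(sample_id = r@sampleId, label = r@label,
               t1m = pp@t1m, t2m = pp@t2m,
               prominence1 = pp@prominence1, prominence2 = pp@prominence2,
               censored1 = pp@censored1, censored2 = pp@censored2,
               complete = !is.na(pp@t1m) && !is.na(pp@t2m))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
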