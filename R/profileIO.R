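#' Read melting scans from CSV
#'
#' Long format (canonical): columns `sample_id, label, temperature, f330,
#' f350` (`label` optional), one row per temperature point. Wide format
#' (read-only): one `temperature` column plus per-sample channel pairs named
#' `<id>_f330` / `<id>_f350`. Per-run invariants (strictly increasing
#' temperatures, positive finite intensities, >= 16 points) are enforced and
#' violations are reported with the offending sample and row.
#'
#' @param path CSV file path.
#' @param dialect "long" or "wide".
#' @return List of [NanoDSFRun-class], sorted by sample id.
#' @seealso [writeRuns()]
#' @export
readRuns <- function(path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (dialect == "long") .readRunsLong(df) else .readRunsWide(df)
}

.readRunsLong <- function(df) {
  need <- c("sample_id", "temperature", "f330", "f350")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  hasLabel <- "label" %in% names(df)
  runs <- lapply(split(seq_len(nrow(df)), df$sample_id), function(rows) {
    sub <- df[rows, ]
    id <- sub$sample_id[1]
    bad <- which(diff(sub$temperature) <= 0)
    if (length(bad))
      stop("sample ", id, ": temperatures not strictly increasing at row ",
           rows[bad[1] + 1])
    bad <- which(!is.finite(sub$f330) | sub$f330 <= 0 |
                 !is.finite(sub$f350) | sub$f350 <= 0)
    if (length(bad))
      stop("sample ", id, ": non-positive or non-finite intensity at row ",
           rows[bad[1]])
    label <- if (hasLabel) as.character(sub$label[1]) else NA_character_
    NanoDSFRun(id, sub$temperature, sub$f330, sub$f350, label = label)
  })
  runs[order(names(runs))]
}

.readRunsWide <- function(df) {
  if (!"temperature" %in% names(df)) stop("missing required column: temperature")
  ch <- grep("_f3(30|50)$", names(df), value = TRUE)
  ids <- sort(unique(sub("_f3(30|50)$", "", ch)))
  if (!length(ids)) stop("no <id>_f330 / <id>_f350 column pairs found")
  lapply(stats::setNames(ids, ids), function(id) {
    c330 <- paste0(id, "_f330")
    c350 <- paste0(id, "_f350")
    if (!all(c(c330, c350) %in% names(df)))
      stop("sample ", id, ": incomplete channel pair")
    NanoDSFRun(id, df$temperature, df[[c330]], df[[c350]])
  })
}

#' Write melting scans to long-format CSV
#'
#' Inverse of [readRuns()] (long dialect). Values are written with 6
#' significant digits; a round trip reproduces runs to that precision.
#'
#' @param runs list of [NanoDSFRun-class].
#' @param path output CSV path.
#' @return Invisibly, the path.
#' @export
writeRuns <- function(runs, path) {
  tabs <- lapply(runs, function(r)
    data.frame(sample_id = r@sampleId, label = r@label,
               temperature = signif(r@temperatures, 6),
               f330 = signif(r@f330, 6), f350 = signif(r@f350, 6)))
  utils::write.csv(do.call(rbind, tabs), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Resample a scan onto a common temperature grid
#'
#' Cubic-spline interpolation (interpolating spline, exact at the original
#' knots and on polynomials up to degree 3) of both channels onto the target
#' grid, which must lie within the run's temperature span -- no
#' extrapolation is performed.
#'
#' @param run a [NanoDSFRun-class].
#' @param grid a [TemperatureGrid-class].
#' @return A [NanoDSFRun-class] on the grid.
#' @export
setGeneric("resampleRun",
           function(run, grid = TemperatureGrid()) standardGeneric("resampleRun"))

#' @rdname resampleRun
setMethod("resampleRun", "NanoDSFRun", function(run, grid) {
  tt <- gridTemps(grid)
  tol <- 1e-9 * diff(range(run@temperatures))
  if (min(tt) < min(run@temperatures) - tol ||
      max(tt) > max(run@temperatures) + tol)
    stop("grid [", min(tt), ", ", max(tt), "] exceeds the span of run ",
         run@sampleId, " [", min(run@temperatures), ", ",
         max(run@temperatures), "]; extrapolation is not allowed")
  s330 <- stats::splinefun(run@temperatures, run@f330, method = "fmm")(tt)
  s350 <- stats::splinefun(run@temperatures, run@f350, method = "fmm")(tt)
  NanoDSFRun(run@sampleId, tt, s330, s350, label = run@label, meta = run@meta)
})

#' Build the six-curve denaturation profile
#'
#' Constructs the full profile of one scan: the two channels resampled onto
#' the grid, their pointwise ratio F350/F330 (formed from the raw resampled
#' channels, before any smoothing, matching the instrument's output order),
#' and the first temperature derivatives of all three obtained by
#' Savitzky-Golay smoothing-differentiation. Within half a filter window of
#' each grid end the derivative comes from one-sided polynomial fits; the
#' half-window is recorded in the result so boundary apexes can be treated
#' as censored peaks downstream.
#'
#' @param run a [NanoDSFRun-class] (any grid within whose span `grid` lies).
#' @param grid target [TemperatureGrid-class].
#' @param window Savitzky-Golay window, degrees C (default 7.0, about twice
#'   the width of a cooperative transition peak: wide enough that spurious
#'   derivative wiggles from instrument-level channel noise stay far below
#'   genuine transition peaks and apex positions are stable to about
#'   0.1 degrees C, while two transitions more than ~6 degrees C apart
#'   remain resolved). Must span at least 3 grid steps.
#' @param polyorder polynomial order of the filter (default 3).
#' @return A [SixCurveSet-class].
#' @examples
#' sc <- sixCurves(simulateScan(mixturePreset("CONTROL"), noiseSigmaRel = 0))
#' sc
#' @export
setGeneric("sixCurves",
  function(run, grid = TemperatureGrid(), window = 7, polyorder = 3L)
    standardGeneric("sixCurves"))

#' @rdname sixCurves
setMethod("sixCurves", "NanoDSFRun", function(run, grid, window, polyorder) {
  if (window < 3 * grid@step)
    stop("smoothing window (", window, " degC) must span at least 3 grid steps")
  tt <- gridTemps(grid)
  onGrid <- length(run@temperatures) == length(tt) &&
    max(abs(run@temperatures - tt)) < 1e-9
  if (!onGrid) run <- resampleRun(run, grid)
  ratio <- run@f350 / run@f330
  np <- floor(window / grid@step)
  if (np %% 2 == 0) np <- np + 1L          # filter length must be odd
  np <- max(np, polyorder + 2 + (polyorder %% 2 == 0))  # enough support
  deriv <- function(y)
    signal::sgolayfilt(y, p = polyorder, n = np, m = 1, ts = grid@step)
  new("SixCurveSet", temperatures = tt, f330 = run@f330, f350 = run@f350,
      ratio = ratio, dF330 = deriv(run@f330), dF350 = deriv(run@f350),
      dRatio = deriv(ratio), edgePoints = as.integer((np - 1) / 2))
})
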