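#' Two-group k-means on the (T1m, T2m) biomarker
#'
#' Lloyd's algorithm with k = 2 on raw, unstandardized degree-Celsius
#' coordinates and squared Euclidean distance. Both biomarker axes are
#' temperatures on comparable scales, so no standardization is applied by
#' default (`standardize = TRUE` z-scores each axis first and maps the
#' centres back). Each restart initialises the two centres at two distinct
#' points sampled without replacement from the set of unique points;
#' iteration stops when assignments stabilise or after 300 rounds; an empty
#' cluster is reseeded to the point farthest from the surviving centre. The
#' best-inertia restart is returned, deterministically for a given seed.
#' The POAG-like cluster is the centre with the lower T1m (in tear cohorts
#' the lower-T1m population is also the higher-T2m one).
#'
#' @param points numeric matrix or data.frame with two columns (t1m, t2m),
#'   finite, at least 2 distinct rows.
#' @param nRestarts number of random restarts (default 50).
#' @param seed integer RNG seed.
#' @param standardize z-score the axes before clustering (default FALSE).
#' @return A [ClusterResult-class].
#' @examples
#' pts <- rbind(matrix(rnorm(40, c(67.9, 77.7), 0.3), ncol = 2, byrow = TRUE),
#'              matrix(rnorm(40, c(64.6, 79.3), 0.3), ncol = 2, byrow = TRUE))
#' kmeansTwo(pts, seed = 1)
#' @export
kmeansTwo <- function(points, nRestarts = 50L, seed = 1L, standardize = FALSE) {
  x <- as.matrix(points)
  if (ncol(x) != 2L) stop("points must have two columns (t1m, t2m)")
  if (!all(is.finite(x))) stop("coordinates must be finite")
  ux <- unique(x)
  if (nrow(ux) < 2L)
    stop("degenerate input: need at least 2 distinct points")
  xWork <- x
  ctr <- c(0, 0); scl <- c(1, 1)
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[scl == 0] <- 1
    xWork <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  }
  # order-invariant restart initialisation: sample from sorted unique points
  uw <- unique(xWork)
  uw <- uw[order(uw[, 1], uw[, 2]), , drop = FALSE]
  best <- NULL
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      init <- sample(nrow(uw), 2L)
      fit <- .lloyd2(xWork, uw[init, , drop = FALSE])
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  centers <- sweep(sweep(best$centers, 2, scl, "*"), 2, ctr, "+")
  colnames(centers) <- c("t1m", "t2m")
  # recompute inertia on the original scale
  inertia <- sum((x - centers[best$assign, , drop = FALSE])^2)
  new("ClusterResult", centers = centers,
      assignments = as.integer(best$assign), inertia = inertia,
      nRestarts = as.integer(nRestarts), seed = as.integer(seed),
      poagLikeCluster = as.integer(which.min(centers[, 1])))
}

.lloyd2 <- function(x, centers, maxIter = 300L) {
  n <- nrow(x)
  assign <- integer(n)
  for (it in seq_len(maxIter)) {
    d1 <- (x[, 1] - centers[1, 1])^2 + (x[, 2] - centers[1, 2])^2
    d2 <- (x[, 1] - centers[2, 1])^2 + (x[, 2] - centers[2, 2])^2
    newAssign <- ifelse(d2 < d1, 2L, 1L)
    for (k in 1:2) {
      if (!any(newAssign == k)) {
        # reseed an emptied centre to the farthest point from the other
        other <- 3L - k
        far <- which.max((x[, 1] - centers[other, 1])^2 +
                         (x[, 2] - centers[other, 2])^2)
        centers[k, ] <- x[far, ]
        newAssign[far] <- k
      }
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (k in 1:2) centers[k, ] <- colMeans(x[assign == k, , drop = FALSE])
  }
  inertia <- sum((x - centers[assign, , drop = FALSE])^2)
  list(centers = centers, assign = assign, inertia = inertia)
}

#' Cluster-by-label contingency and positive fractions
#'
#' Cross-tabulates cluster assignments against class labels and reports, per
#' label, the fraction of its samples falling into the POAG-like (lower-T1m)
#' cluster -- the "positive" call of the two-parameter clustering.
#'
#' @param result a [ClusterResult-class].
#' @param labels character or factor, aligned with the clustered samples.
#' @return List with `table` (cluster x label counts) and
#'   `positiveFraction` (named per label).
#' @export
crossTab <- function(result, labels) {
  stopifnot(is(result, "ClusterResult"))
  if (length(labels) != length(result@assignments))
    stop("labels length (", length(labels),
         ") does not match assignments (", length(result@assignments), ")")
  tab <- table(cluster = result@assignments, label = as.character(labels))
  pos <- result@poagLikeCluster
  frac <- vapply(colnames(tab), function(l) {
    tot <- sum(tab[, l])
    if (tot == 0) NA_real_
    else sum(tab[rownames(tab) == as.character(pos), l]) / tot
  }, numeric(1))
  list(table = tab, positiveFraction = frac)
}
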