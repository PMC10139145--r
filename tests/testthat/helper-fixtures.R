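# Shared fixtures, built in code.

singleSpeciesRun <- function(name, conc = 100, ligand = NULL, noise = 0,
                             seed = 1L) {
  ligands <- if (is.null(ligand)) list() else list(getLigand(ligand))
  mix <- MixtureSpec(getSpecies(name), conc, ligands = ligands, name = name)
  simulateScan(mix, noiseSigmaRel = noise, seed = seed)
}

detectFromRun <- function(run, ...) detectPeaks(sixCurves(run), ...)

# A SixCurveSet whose ratio derivative is fully under test control.
syntheticCurveSet <- function(dRatio, grid = TemperatureGrid()) {
  tt <- gridTemps(grid)
  ones <- rep(1, length(tt))
  new("SixCurveSet", temperatures = tt, f330 = ones, f350 = ones,
      ratio = ones, dF330 = numeric(length(tt)), dF350 = numeric(length(tt)),
      dRatio = dRatio, edgePoints = 0L)
}

smallSeparatedConfig <- function(n = 15L, seed = 5L, noise = 1e-4) {
  CohortConfig(meanT1m = c(CONTROL = 68, POAG = 60),
               meanT2m = c(CONTROL = 78, POAG = 86),
               sdT1m = c(CONTROL = 0.5, POAG = 0.5),
               sdT2m = c(CONTROL = 0.5, POAG = 0.5),
               n = c(CONTROL = n, POAG = n),
               noiseSigmaRel = noise, seed = seed)
}

# Adjusted Rand index between two labellings (closed-form from the
# pair-counting contingency table); independent of any clustering code.
adjustedRand <- function(a, b) {
  tab <- table(a, b)
  sumij <- sum(choose(tab, 2))
  sumi <- sum(choose(rowSums(tab), 2))
  sumj <- sum(choose(colSums(tab), 2))
  npairs <- choose(sum(tab), 2)
  expected <- sumi * sumj / npairs
  (sumij - expected) / ((sumi + sumj) / 2 - expected)
}

# Exhaustive best 2-partition by within-cluster sum of squares.
bruteForceTwoMeans <- function(x) {
  n <- nrow(x)
  best <- Inf
  bestAssign <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {   # fix point 1 in cluster 1; skip empties
    assign <- as.integer(intToBits(mask))[seq_len(n)] + 1L
    if (length(unique(assign)) < 2L) next
    inertia <- sum(vapply(1:2, function(k) {
      xs <- x[assign == k, , drop = FALSE]
      sum(sweep(xs, 2, colMeans(xs))^2)
    }, numeric(1)))
    if (inertia < best) { best <- inertia; bestAssign <- assign }
  }
  list(inertia = best, assign = bestAssign)
}
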