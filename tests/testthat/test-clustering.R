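makeClouds <- function(n = 40, sd = 0.3, seed = 21,
                       mu1 = c(67.9, 77.7), mu2 = c(64.6, 79.3)) {
  set.seed(seed)
  x <- rbind(cbind(rnorm(n, mu1[1], sd), rnorm(n, mu1[2], sd)),
             cbind(rnorm(n, mu2[1], sd), rnorm(n, mu2[2], sd)))
  list(x = x, truth = rep(1:2, each = n))
}

test_that("two tight clouds at the tear-cluster averages are recovered exactly", {
  cl <- makeClouds()
  res <- kmeansTwo(cl$x, seed = 1L)
  centers <- clusterCenters(res)
  poag <- poagLikeCluster(res)
  expect_lte(max(abs(centers[poag, ] - c(64.6, 79.3))), 0.2)
  expect_lte(max(abs(centers[3 - poag, ] - c(67.9, 77.7))), 0.2)
  expect_equal(adjustedRand(clusterAssignments(res), cl$truth), 1)
  # POAG-like is, by definition, the lower-T1m centre
  expect_equal(poag, unname(which.min(centers[, "t1m"])))
})

test_that("the partition matches the exhaustive two-partition optimum", {
  pts <- matrix(c(64.1, 79.0, 64.9, 79.5, 65.2, 78.8,
                  67.8, 77.5, 68.3, 77.9, 69.0, 77.2),
                ncol = 2, byrow = TRUE)
  res <- kmeansTwo(pts, seed = 2L)
  oracle <- bruteForceTwoMeans(pts)
  expect_equal(res@inertia, oracle$inertia, tolerance = 1e-12)
  expect_equal(adjustedRand(clusterAssignments(res), oracle$assign), 1)
})

test_that("duplicating every point leaves the centres unchanged", {
  cl <- makeClouds(n = 15)
  res1 <- kmeansTwo(cl$x, seed = 3L)
  res2 <- kmeansTwo(rbind(cl$x, cl$x), seed = 3L)
  o1 <- order(clusterCenters(res1)[, 1])
  o2 <- order(clusterCenters(res2)[, 1])
  expect_equal(clusterCenters(res1)[o1, ], clusterCenters(res2)[o2, ],
               tolerance = 1e-9)
})

test_that("the returned solution is the best over restarts", {
  cl <- makeClouds(n = 20, sd = 1.5, seed = 5)
  best <- kmeansTwo(cl$x, nRestarts = 50L, seed = 1L)@inertia
  singles <- vapply(1:10, function(s)
    kmeansTwo(cl$x, nRestarts = 1L, seed = s)@inertia, numeric(1))
  expect_true(all(best <= singles + 1e-9))
})

test_that("clustering agrees with the reference k-means on separated data", {
  cl <- makeClouds()
  res <- kmeansTwo(cl$x, seed = 4L)
  ref <- stats::kmeans(cl$x, centers = 2L, nstart = 10L)
  expect_equal(adjustedRand(clusterAssignments(res), ref$cluster), 1)
  expect_equal(sort(clusterCenters(res)[, 1]), sort(ref$centers[, 1]),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("results are deterministic in the seed and invariant to row order", {
  cl <- makeClouds(n = 12, sd = 1.0, seed = 7)
  a <- kmeansTwo(cl$x, seed = 5L)
  b <- kmeansTwo(cl$x, seed = 5L)
  expect_identical(clusterAssignments(a), clusterAssignments(b))
  perm <- sample(nrow(cl$x))
  c <- kmeansTwo(cl$x[perm, ], seed = 5L)
  o1 <- order(clusterCenters(a)[, 1])
  o2 <- order(clusterCenters(c)[, 1])
  expect_equal(clusterCenters(a)[o1, ], clusterCenters(c)[o2, ],
               tolerance = 1e-9)
  expect_equal(adjustedRand(clusterAssignments(c),
                            clusterAssignments(a)[perm]), 1)
})

test_that("degenerate inputs are rejected", {
  same <- matrix(rep(c(65, 78), 5), ncol = 2, byrow = TRUE)
  expect_error(kmeansTwo(same), "degenerate")
  expect_error(kmeansTwo(matrix(c(1, NA, 2, 3), ncol = 2)), "finite")
  expect_error(kmeansTwo(matrix(1:9, ncol = 3)), "two columns")
})

test_that("contingency reporting gives per-label positive fractions", {
  cl <- makeClouds()
  res <- kmeansTwo(cl$x, seed = 1L)
  labels <- c(rep("CONTROL", 40), rep("POAG", 40))
  ct <- crossTab(res, labels)
  expect_equal(unname(ct$positiveFraction[["POAG"]]), 1)
  expect_equal(unname(ct$positiveFraction[["CONTROL"]]), 0)
  expect_equal(sum(ct$table), 80)

  one <- crossTab(res, rep("POAG", 80))
  expect_equal(unname(one$positiveFraction[["POAG"]]), 0.5)

  # randomized labels: positive fraction approximates the cluster share
  set.seed(9)
  rnd <- sample(labels)
  ctr <- crossTab(res, rnd)
  share <- mean(clusterAssignments(res) == poagLikeCluster(res))
  tol <- 3 * sqrt(share * (1 - share) / 40)
  expect_lte(abs(ctr$positiveFraction[["POAG"]] - share), tol)
  expect_error(crossTab(res, labels[1:10]), "does not match")
})

test_that("standardized clustering is exposed and consistent here", {
  cl <- makeClouds()
  res <- kmeansTwo(cl$x, seed = 1L, standardize = TRUE)
  expect_equal(adjustedRand(clusterAssignments(res), cl$truth), 1)
  expect_lte(max(abs(clusterCenters(res)[poagLikeCluster(res), ] -
                       c(64.6, 79.3))), 0.2)
})
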