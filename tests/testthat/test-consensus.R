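test_that("proximity clustering follows the linking radius", {
  two <- data.frame(row = c(10, 10), col = c(10, 11), annotator = c("a", "b"))
  cl <- clusterDetections(two, linkRadius = 1.5)
  expect_equal(nrow(cl$centroids), 1)
  expect_equal(unname(unlist(cl$centroids)), c(10, 10.5))

  apart <- data.frame(row = c(10, 10), col = c(10, 12), annotator = c("a", "b"))
  expect_equal(nrow(clusterDetections(apart, 1.5)$centroids), 2)

  # transitive chain: A-B and B-C linked, A-C not, still one component
  chain <- data.frame(row = c(10, 10, 10), col = c(10, 11.4, 12.8),
                      annotator = c("a", "b", "c"))
  cl <- clusterDetections(chain, 1.5)
  expect_equal(nrow(cl$centroids), 1)
  expect_equal(sum(cl$members$cluster == 1), 3)

  expect_error(clusterDetections(two, linkRadius = 0), "linkRadius")
})

test_that("clustering matches an exhaustive union-find oracle", {
  for (s in 1:20) {
    ann <- randomAnnotations(60, c("a", "b", "c"), extent = 25, seed = 100 + s)
    cl <- clusterDetections(ann, 1.5)
    oracle <- unionFindClusters(ann, 1.5)
    # same partition before screening splits: compare co-membership of pairs
    # not affected by screening (screening only splits same-annotator dupes)
    oracleSizes <- sort(table(oracle))
    # rebuild oracle partition with the same screening rule applied
    memb <- cl$members
    # every package cluster must be a subset of one oracle component
    for (k in unique(memb$cluster)) {
      idx <- which(memb$cluster == k)
      expect_equal(length(unique(oracle[idx])), 1)
    }
    # and clusters are screened
    expect_false(anyDuplicated(memb[, c("cluster", "annotator")]) > 0)
  }
})

test_that("screening keeps the member closest to the centroid", {
  ann <- data.frame(row = c(10, 10, 10), col = c(10, 10.9, 11.5),
                    annotator = c("a", "a", "b"))
  cl <- clusterDetections(ann, 1.5)
  # component centroid (10, 10.8): the annotator-a member at 10.9 is closer;
  # the one at 10.0 splits into a singleton
  expect_equal(nrow(cl$centroids), 2)
  m <- cl$members
  kept <- m[m$annotator == "a" & m$cluster == m$cluster[m$annotator == "b"], ]
  expect_equal(kept$col, 10.9)
  # centroids are recomputed from retained members only
  expect_true(any(abs(cl$centroids$col - mean(c(10.9, 11.5))) < 1e-9))
})

test_that("the detection information matrix records cluster membership", {
  ann <- data.frame(row = c(10, 10, 10, 30), col = c(10, 10.5, 11, 30),
                    annotator = c("a", "b", "c", "b"))
  cl <- clusterDetections(ann, 1.5)
  x <- buildDetectionMatrix(cl, c("a", "b", "c"))
  expect_equal(dim(x), c(2, 3))
  expect_true(all(rowSums(x) >= 1))
  full <- x[rowSums(x) == 3, ]
  expect_equal(unname(full), c(1, 1, 1))
  singleton <- x[rowSums(x) == 1, ]
  expect_equal(unname(singleton), c(0, 1, 0))

  # row sums recount cluster sizes on random screened sets
  ann <- randomAnnotations(80, c("a", "b", "c", "d"), extent = 30, seed = 7)
  cl <- clusterDetections(ann, 1.5)
  x <- buildDetectionMatrix(cl)
  expect_equal(unname(rowSums(x)),
               unname(as.vector(table(cl$members$cluster))))

  fake <- cl
  fake$members <- rbind(fake$members,
                        transform(fake$members[1, ], row = row + 0.1))
  expect_error(buildDetectionMatrix(fake), "duplicate")
})

test_that("the expectation step reproduces hand-computed posteriors", {
  x1 <- matrix(1, 1, 1)
  expect_equal(eStep(x1, 0.9, 0.1, prior = 0.5), 0.9)

  x3 <- matrix(1, 1, 3)
  p <- eStep(x3, rep(0.9, 3), rep(0.1, 3), 0.5)
  expect_equal(p, 0.729 / (0.729 + 0.001), tolerance = 1e-12)

  # uninformative annotators leave the posterior at the prior
  x <- matrix(rbinom(40, 1, 0.5), 10, 4)
  expect_equal(eStep(x, rep(0.7, 4), rep(0.7, 4), 0.5), rep(0.5, 10))

  expect_error(eStep(x1, 1, 0.1), "strictly")
})

test_that("the maximization step accumulates expected confusion counts", {
  x <- matrix(c(1, 0), 2, 1)            # annotator detects only cluster 1
  up <- mStep(x, c(0.8, 0.4))
  expect_equal(unname(up$tpr), 0.8 / (0.8 + 0.4), tolerance = 1e-12)
  expect_equal(unname(up$fpr), 0.2 / (0.2 + 0.6), tolerance = 1e-12)

  # detecting everything forces EFN = 0, hence TPR at the clamp ceiling
  xall <- matrix(1, 5, 1)
  up <- mStep(xall, runif(5))
  expect_equal(unname(up$tpr), 1 - 1e-4)

  # degenerate: all-zero posteriors and no detections
  expect_warning(up <- mStep(matrix(0, 3, 1), c(0, 0, 0)))
  expect_equal(unname(up$tpr), 0.5)
})

test_that("EM recovers simulated annotator parameters and labels", {
  s <- simulateDetectionMatrix(4000, rep(0.9, 4), rep(0.1, 4), 0.5, seed = 21)
  fit <- fitEM(s$x)
  expect_true(all(abs(tpr(fit) - 0.9) < 0.05))
  expect_true(all(abs(fpr(fit) - 0.1) < 0.05))
  acc <- mean((posteriorProb(fit) > 0.5) == (s$z == 1))
  expect_gt(acc, 0.93)

  # noiseless annotators give exact labels
  s0 <- simulateDetectionMatrix(500, rep(1 - 1e-9, 3), rep(1e-9, 3), 0.5, seed = 22)
  fit0 <- fitEM(s0$x)
  expect_equal((posteriorProb(fit0) > 0.5) * 1, s0$z)

  # all-ones matrix: posterior stays at the uninformative fixed point
  fit1 <- fitEM(matrix(1, 50, 3))
  expect_equal(unname(posteriorProb(fit1)), rep(0.5, 50), tolerance = 1e-6)

  expect_error(fitEM(s$x, nIter = 0), "nIter")
})

test_that("the EM log-likelihood never decreases", {
  set.seed(31)
  for (k in 1:10) {
    s <- simulateDetectionMatrix(300, runif(3, 0.6, 0.95), runif(3, 0.02, 0.3),
                                 runif(1, 0.2, 0.8), seed = 300 + k)
    fit <- fitEM(s$x, nIter = 20)
    expect_true(all(diff(fit@logLik) >= -1e-9))
  }
})

test_that("annotator order is exchangeable", {
  s <- simulateDetectionMatrix(1000, c(0.95, 0.8, 0.7), c(0.05, 0.15, 0.2),
                               0.5, seed = 41)
  fit <- fitEM(s$x)
  perm <- c(3, 1, 2)
  fitP <- fitEM(s$x[, perm])
  expect_equal(unname(tpr(fitP)), unname(tpr(fit)[perm]), tolerance = 1e-12)
  expect_equal(unname(fpr(fitP)), unname(fpr(fit)[perm]), tolerance = 1e-12)
  expect_equal(posteriorProb(fitP), posteriorProb(fit), tolerance = 1e-12)
})

test_that("consensus extraction thresholds the posterior", {
  cl <- clusterDetections(data.frame(row = c(5, 5, 20, 20),
                                     col = c(5, 5.4, 20, 20.4),
                                     annotator = c("a", "b", "a", "b")), 1.5)
  sp <- extractConsensus(cl, c(0.95, 0.5), threshold = 0.9)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$p_tp, 0.95)
  sp <- extractConsensus(cl, c(0.95, 0.5), threshold = 0)
  expect_equal(nrow(sp), 2)
  expect_error(extractConsensus(cl, c(0.95, 0.5), threshold = 1.2), "threshold")

  # retained count equals a brute-force recount on a random posterior
  set.seed(51)
  ann <- randomAnnotations(60, c("a", "b"), extent = 50, seed = 51)
  cl <- clusterDetections(ann, 1.5)
  p <- runif(nrow(cl$centroids))
  expect_equal(nrow(extractConsensus(cl, p, 0.7)), sum(p > 0.7))
})
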