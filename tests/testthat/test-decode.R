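test_that("the relaxed Bernoulli density matches its analytic distribution", {
  # closed-form CDF of the binary Concrete: F(x) = sigmoid(lambda*logit(x)
  # - logit(alpha)); the numeric integral of the density must reproduce it
  concreteCDF <- function(x, al, lam) plogis(lam * qlogis(x) - qlogis(al))
  a <- 1e-4; b <- 1 - 1e-4
  for (al in c(0.2, 0.5, 0.9)) for (lam in c(0.5, 1, 2)) {
    z <- integrate(function(x) dRelaxedBernoulli(x, al, lam), a, b,
                   rel.tol = 1e-9)
    expect_equal(z$value, concreteCDF(b, al, lam) - concreteCDF(a, al, lam),
                 tolerance = 1e-5)
  }
  # mass shifts toward 1 as alpha grows
  expect_gt(dRelaxedBernoulli(0.9, 0.9, 1), dRelaxedBernoulli(0.9, 0.1, 1))
  expect_error(dRelaxedBernoulli(0.5, 1.5, 1), "alpha")
  expect_error(dRelaxedBernoulli(0.5, 0.5, -1), "lambda")
})

test_that("codebooks validate their structure and round-trip through files", {
  cb <- randomCodebook(12, 2, 4, 3, minHamming = 2, seed = 1)
  expect_equal(length(geneNames(cb)), 12)
  expect_equal(dim(barcodeMatrix(cb, withBackground = TRUE)), c(13, 8))
  expect_true(all(barcodeMatrix(cb, TRUE)[13, ] == 0))
  expect_true(all(rowSums(barcodeMatrix(cb)) == 3))
  # pairwise distance respects the floor
  B <- barcodeMatrix(cb)
  d <- as.matrix(dist(B, method = "manhattan")); diag(d) <- Inf
  expect_true(min(d) >= 2)

  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  writeCodebook(cb, csv); writeCodebook(cb, js)
  for (p in c(csv, js)) {
    cb2 <- readCodebook(p)
    expect_equal(barcodeMatrix(cb2), barcodeMatrix(cb), ignore_attr = TRUE)
    expect_equal(geneNames(cb2), geneNames(cb))
  }
  bad <- read.csv(csv, check.names = FALSE); bad[1, 2] <- 0.5
  f <- tempfile(fileext = ".csv"); write.csv(bad, f, row.names = FALSE)
  expect_error(readCodebook(f), "non-binary")
})

test_that("decodable pixel selection thresholds the max projection", {
  st <- array(0, c(6, 7, 4))
  expect_equal(nrow(selectDecodablePixels(st)$coords), 0)

  st[3, 5, 2] <- 0.9
  px <- selectDecodablePixels(st)
  expect_equal(nrow(px$coords), 1)
  expect_equal(c(px$coords$row, px$coords$col), c(3, 5))
  expect_equal(px$traces[1, ], c(0, 0.9, 0, 0))

  set.seed(91)
  st <- array(runif(6 * 7 * 4) * 0.05, c(6, 7, 4))
  px <- selectDecodablePixels(st, 0.03)
  expect_equal(nrow(px$coords), sum(apply(st, c(1, 2), max) > 0.03))
})

test_that("the mixture fit separates spot and background distributions", {
  cb <- randomCodebook(20, 4, 4, 4, minHamming = 4, seed = 2)
  st <- simulateBarcodeTraces(cb, 1500, seed = 3)
  mix <- fitBarcodeMixture(st, cb, steps = 500, seed = 4)
  expect_true(mean(mix$alphaSpot) > 0.8)
  expect_true(mean(mix$alphaBg) < 0.2)
  expect_true(all(mix$alphaSpot > mix$alphaBg))
  expect_gt(mix$temperature, 0)
  # the recorded log evidence improves over optimization
  expect_gt(tail(mix$logLik, 1), mix$logLik[1])

  # deterministic given the seed
  mix2 <- fitBarcodeMixture(st, cb, steps = 500, seed = 4)
  expect_identical(mix$alphaSpot, mix2$alphaSpot)

  g <- fitBarcodeMixture(st, cb, family = "gaussian", steps = 60)
  expect_true(all(g$muSpot > g$muBg))
  b <- fitBarcodeMixture(st, cb, family = "bernoulli", steps = 60)
  expect_true(all(b$alphaSpot > b$alphaBg))
})

test_that("the degenerate single-gene fit matches a direct MLE oracle", {
  cb <- Codebook("g1", matrix(c(1, 1, 1, 1, 0, 0, 0, 0), 1, 8), 2, 4)
  set.seed(5)
  tr <- matrix(0.05, 400, 8)
  tr[, 1:4] <- matrix(rbeta(1600, 200, 10), 400, 4)
  mix <- fitBarcodeMixture(tr, cb, steps = 800, seed = 6)
  # oracle: joint single-distribution MLE of the relaxed Bernoulli on the
  # on-bit values (alpha via its logit, shared temperature)
  onv <- pmin(pmax(as.vector(tr[, 1:4]), 1e-4), 1 - 1e-4)
  nll <- function(p) {
    al <- min(max(plogis(p[1]), 1e-6), 1 - 1e-6)
    lam <- min(max(exp(p[2]), 1e-6), 1e6)
    -sum(dRelaxedBernoulli(onv, al, lam, log = TRUE))
  }
  o <- optim(c(0, 0), nll, method = "BFGS")
  alphaOracle <- plogis(o$par[1])
  expect_lt(abs(mean(mix$alphaSpot[1:4]) - alphaOracle), 0.05)
})

test_that("barcode assignment computes normalized posteriors and statuses", {
  cb <- Codebook(c("g1", "g2"), rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 2, 2)
  params <- structure(list(family = "relaxed_bernoulli",
                           alphaSpot = rep(0.95, 4), alphaBg = rep(0.05, 4),
                           temperature = 1), class = "BarcodeMixture")
  tr <- rbind(c(0.95, 0.95, 0.05, 0.05),    # exactly g1
              c(0.05, 0.05, 0.05, 0.05),    # background
              c(0.95, 0.05, 0.05, 0.95))    # symmetric between g1 and g2
  asg <- assignBarcodes(tr, params, cb)
  expect_equal(asg$gene[1], "g1")
  expect_gt(asg$probability[1], 0.99)
  expect_equal(asg$status[1], "assigned")
  expect_equal(asg$gene[2], "background")
  expect_equal(asg$status[3], "unknown")
  post <- attr(asg, "posterior")
  expect_equal(unname(rowSums(post)), rep(1, 3), tolerance = 1e-8)
  expect_equal(unname(post[3, 1]), unname(post[3, 2]), tolerance = 1e-9)
})

test_that("error rescue reassigns unique Hamming-1 neighbors only", {
  cb <- randomCodebook(15, 4, 4, 4, minHamming = 4, seed = 7)
  B <- barcodeMatrix(cb)
  mkTrace <- function(bits) ifelse(bits == 1, 0.95, 0.05)

  # one dropped bit: unique neighbor at distance 1 -> rescued
  b1 <- B[3, ]; drop1 <- b1; drop1[which(b1 == 1)[1]] <- 0
  # distance 2 from everything: untouched
  b2 <- B[5, ]; far <- b2; far[which(b2 == 1)[1:2]] <- 0
  tr <- rbind(mkTrace(drop1), mkTrace(far))
  asg <- data.frame(row = NA, col = NA, gene = "background",
                    geneIndex = nrow(B) + 1, probability = 0.5,
                    status = c("background", "unknown"))
  out <- errorRescue(asg, tr, cb)
  expect_equal(out$status[1], "rescued_error")
  expect_equal(out$gene[1], geneNames(cb)[3])
  expect_equal(out$status[2], "unknown")

  # ambiguity: two barcodes at the same minimal distance block the rescue
  cbA <- Codebook(c("a", "b"), rbind(c(1, 1, 0, 0, 0, 0), c(1, 0, 1, 0, 0, 0)),
                  2, 3)
  mid <- mkTrace(c(1, 0, 0, 0, 0, 0))      # distance 1 from both
  asgA <- data.frame(row = NA, col = NA, gene = "background", geneIndex = 3,
                     probability = 0.5, status = "background")
  expect_equal(errorRescue(asgA, rbind(mid), cbA)$status, "background")
})

test_that("mixed rescue recovers overlapping barcode pairs", {
  cb <- Codebook(c("a", "b", "c"),
                 rbind(c(1, 1, 0, 0, 0, 0, 0, 0),
                       c(0, 0, 1, 1, 0, 0, 0, 0),
                       c(0, 0, 0, 0, 1, 1, 0, 0)), 2, 4)
  union <- ifelse(c(1, 1, 1, 1, 0, 0, 0, 0) == 1, 0.95, 0.05)
  asg <- data.frame(row = 3, col = 4, gene = "a", geneIndex = 1,
                    probability = 0.6, status = "unknown")
  out <- mixedRescue(asg, rbind(union), cb)
  expect_equal(nrow(out), 2)
  expect_true(all(out$status == "rescued_mixed"))
  expect_setequal(out$gene, c("a", "b"))

  # replace-only mode keeps a single row
  out2 <- mixedRescue(asg, rbind(union), cb, replace = TRUE)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$gene, "b")

  # residual of zeros: no second transcript
  pure <- ifelse(c(1, 1, 0, 0, 0, 0, 0, 0) == 1, 0.95, 0.05)
  expect_equal(nrow(mixedRescue(asg, rbind(pure), cb)), 1)

  # residual far from every other barcode: no second transcript
  stray <- ifelse(c(1, 1, 0, 1, 1, 1, 1, 0) == 1, 0.95, 0.05)
  out3 <- mixedRescue(asg, rbind(stray), cb)
  expect_equal(nrow(out3), 1)
})

test_that("background masking removes items under bright structures", {
  spots <- data.frame(row = c(5, 10, 15, 20), col = c(5, 10, 15, 20))
  bg <- matrix(0, 24, 24)
  expect_equal(nrow(applyBackgroundMask(spots, bg)), 4)

  bg[4:11, 4:11] <- 1                       # blob covers the first two spots
  out <- applyBackgroundMask(spots, bg)
  expect_equal(out$row, c(15, 20))

  expect_equal(nrow(applyBackgroundMask(spots, bg, threshold = 1)), 4)

  # logical masks are accepted directly
  m <- matrix(FALSE, 24, 24); m[15, 15] <- TRUE
  expect_equal(nrow(applyBackgroundMask(spots, m)), 3)
})

test_that("decoded spots are extracted at masked probability maxima", {
  st <- array(0.0, c(12, 12, 4))
  st[5:6, 5:6, 1] <- 0.6; st[5, 5, 1] <- 0.9        # one blob, peak at (5,5)
  st[10, 10, 2] <- 0.8                               # second blob
  asg <- data.frame(row = c(5, 5, 6, 6, 10), col = c(5, 6, 5, 6, 10),
                    gene = c("a", "a", "a", "a", "b"), geneIndex = 1,
                    probability = 0.99, status = "assigned")
  ds <- extractDecodedSpots(asg, st)
  df <- decodedSpots(ds)
  expect_equal(nrow(df), 2)
  expect_setequal(df$gene, c("a", "b"))
  expect_equal(df$row[df$gene == "a"], 5)

  none <- asg; none$status <- "unknown"
  expect_equal(nrow(decodedSpots(extractDecodedSpots(none, st))), 0)
})

test_that("transcripts aggregate into a cell-by-gene table", {
  mask <- matrix(0L, 20, 20)
  mask[1:8, 1:8] <- 1L; mask[12:18, 12:18] <- 2L
  spots <- data.frame(row = c(3, 4, 14, 19.6), col = c(3, 5, 15, 19.6),
                      gene = c("g1", "g2", "g1", "g1"))
  out <- assignToCells(spots, mask)
  expect_equal(out$spots$cell_id, c(1L, 1L, 2L, 0L))
  counts <- out$counts
  expect_equal(unname(counts["1", "g1"]), 1)
  expect_equal(unname(counts["1", "g2"]), 1)
  expect_equal(unname(counts["2", "g1"]), 1)
  expect_equal(unname(counts["0", "g1"]), 1)
  # table equals a brute-force tally
  tal <- table(out$spots$cell_id, out$spots$gene)
  expect_equal(sum(counts), sum(tal))
})
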