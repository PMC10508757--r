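test_that("preprocessing clips percentiles and scales to [0, 1]", {
  set.seed(71)
  img <- matrix(runif(10000), 100, 100)
  out <- preprocessImage(img)
  expect_true(all(out >= 0 & out <= 1))

  # a single extreme outlier is clipped to the 99.9th percentile: it maps to
  # the same value as every pixel at or above that percentile
  img2 <- img; img2[50, 50] <- 1e6
  out2 <- preprocessImage(img2)
  expect_equal(out2[50, 50], 1)
  expect_equal(sum(out2 == 1), sum(img2 >= quantile(img2, 0.999)))

  expect_warning(z <- preprocessImage(matrix(3, 5, 5)), "constant")
  expect_equal(z, matrix(0, 5, 5))
})

test_that("target encoding places one-hot pixels and signed offsets", {
  t1 <- makeTargets(data.frame(row = 5, col = 7), c(12, 12))
  expect_equal(which(t1$classification == 1), 5 + (7 - 1) * 12)
  expect_equal(t1$dy[5, 7], 0)
  expect_equal(t1$dx[5, 7], 0)

  t2 <- makeTargets(data.frame(row = 5.3, col = 7.8), c(12, 12))
  expect_equal(which(t2$classification == 1, arr.ind = TRUE)[1, ],
               c(row = 5, col = 8))
  expect_equal(t2$dy[5, 8], 0.3)
  expect_equal(t2$dx[5, 8], -0.2)
  # offsets at positive pixels never exceed half a pixel
  expect_true(all(abs(t2$dy[t2$classification == 1]) <= 0.5))

  t0 <- makeTargets(data.frame(row = numeric(0), col = numeric(0)), c(8, 8))
  expect_true(all(t0$classification == 0))
  expect_false(any(t0$mask))

  expect_warning(makeTargets(data.frame(row = c(5.1, 5.2), col = c(7, 7.1)),
                             c(12, 12)), "one pixel")
  expect_error(makeTargets(data.frame(row = 50, col = 1), c(12, 12)), "bounds")
})

test_that("the network is fully convolutional with the configured receptive field", {
  expect_error(buildSpotNet(12), "odd")
  net <- buildSpotNet(13, 6, seed = 1)
  expect_equal(net@config$depth * 2 + 1, 13)

  # output shapes track input shapes
  for (sz in c(64, 33)) {
    p <- predictSpotNet(net, matrix(runif(sz * sz), sz, sz))
    expect_equal(dim(p@probability), c(sz, sz))
    expect_equal(dim(p@dy), c(sz, sz))
  }

  # translation equivariance on interior pixels
  set.seed(2)
  img <- matrix(runif(64 * 64), 64, 64)
  shifted <- matrix(0, 64, 64)
  shifted[6:64, ] <- img[1:59, ]
  a <- predictSpotNet(net, img)@probability
  b <- predictSpotNet(net, shifted)@probability
  expect_equal(b[20:50, 10:55], a[15:45, 10:55], tolerance = 1e-10)
})

test_that("perturbations outside the receptive field cannot reach a pixel", {
  net <- buildSpotNet(13, 6, seed = 3)
  set.seed(4)
  img <- matrix(runif(41 * 41), 41, 41)
  base <- predictSpotNet(net, img)@probability[21, 21]
  inRF <- img; inRF[21 + 5, 21] <- inRF[21 + 5, 21] + 10
  outRF <- img; outRF[21 + 7, 21] <- outRF[21 + 7, 21] + 10
  expect_false(isTRUE(all.equal(predictSpotNet(net, inRF)@probability[21, 21], base)))
  expect_equal(predictSpotNet(net, outRF)@probability[21, 21], base, tolerance = 1e-12)
})

test_that("the loss decomposes into weighted cross entropy and masked MSE", {
  tg <- makeTargets(data.frame(row = c(4.2, 9.7), col = c(5.1, 10.4)), c(14, 14))
  ideal <- idealPrediction(tg)
  l <- spotNetLoss(ideal, tg)
  expect_lt(l$classification, 1e-5)
  expect_equal(l$regression, 0)

  # regression error strictly outside the mask contributes nothing
  bad <- ideal
  bad@dy[!tg$mask] <- bad@dy[!tg$mask] + 5
  expect_equal(spotNetLoss(bad, tg)$regression, 0)

  # hand-computed single-pixel errors
  tgs <- makeTargets(data.frame(row = 4, col = 4), c(7, 7), regressionRadius = 1)
  pred <- idealPrediction(tgs)
  pred@probability[1, 1] <- 0.5           # one wrong background pixel
  pred@dy[4, 4] <- 0.25                   # one masked regression error
  l <- spotNetLoss(pred, tgs, posWeight = 10)
  nPix <- 49
  wSum <- 10 * 1 + (nPix - 1) * 1
  ceHand <- (-log(1 - 0.5) - log(1 - 1e-7) * (nPix - 2) - 10 * log(1 - 1e-7)) / wSum
  mseHand <- 0.25^2 / (2 * sum(tgs$mask))
  expect_equal(l$classification, ceHand, tolerance = 1e-6)
  expect_equal(l$regression, mseHand, tolerance = 1e-12)
})

test_that("postprocessing adds regression offsets at probability maxima", {
  prob <- matrix(0, 16, 16); prob[8, 9] <- 1
  pred <- new("SpotPrediction", probability = prob,
              dy = matrix(0, 16, 16), dx = matrix(0, 16, 16))
  out <- postprocessPrediction(pred)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$row, out$col), c(8, 9))

  pred@dy[8, 9] <- 0.3; pred@dx[8, 9] <- -0.2
  out <- postprocessPrediction(pred)
  expect_equal(c(out$row, out$col), c(8.3, 8.8))

  pred@probability[8, 9] <- 0.9
  expect_equal(nrow(postprocessPrediction(pred, threshold = 0.95)), 0)
})

test_that("targets and postprocessing round-trip subpixel coordinates", {
  for (s in 1:10) {
    spots <- gridSpots(c(48, 48), seed = 400 + s)
    tg <- makeTargets(spots, c(48, 48))
    rec <- postprocessPrediction(idealPrediction(tg), threshold = 0.5)
    expect_equal(nrow(rec), nrow(spots))
    ord <- order(rec$row, rec$col); os <- order(spots$row, spots$col)
    expect_lt(max(abs(rec$row[ord] - spots$row[os])), 1e-6)
    expect_lt(max(abs(rec$col[ord] - spots$col[os])), 1e-6)
  }
})

test_that("training reduces the loss deterministically", {
  set.seed(81)
  sims <- lapply(1:14, function(i) simulateSpotImage(c(32, 32), c(6, 12),
                                                     seed = 500 + i))
  imgs <- lapply(sims, function(s) preprocessImage(s$pixels))
  spts <- lapply(sims, function(s) s$truth[, c("row", "col")])
  net <- buildSpotNet(9, 6, seed = 1)

  net0 <- trainSpotNet(net, imgs, spts, epochs = 0, seed = 1)
  expect_identical(net0@params, net@params)

  netA <- suppressWarnings(trainSpotNet(net, imgs, spts, epochs = 4,
                                        batchSize = 4, seed = 2))
  expect_true(netA@trained)
  expect_lt(netA@history$trainLoss[4], netA@history$trainLoss[1])

  netB <- suppressWarnings(trainSpotNet(net, imgs, spts, epochs = 1,
                                        batchSize = 4, seed = 2))
  expect_equal(netB@history$trainLoss[1], netA@history$trainLoss[1],
               tolerance = 1e-12)
})
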