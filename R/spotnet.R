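#' Preprocess an image for detection
#'
#' Clips pixel intensities at the 0.1 and 99.9 percentiles, then min-max
#' scales to \[0, 1\]. A constant image cannot be scaled and comes back as
#' all zeros with a warning.
#'
#' @param image 2-D numeric matrix.
#' @return matrix of the same shape with values in \[0, 1\].
#' @export
preprocessImage <- function(image) {
  .stopifnot2(is.matrix(image) && length(image) > 0, "image must be a non-empty matrix")
  q <- quantile(image, c(0.001, 0.999), names = FALSE)
  img <- pmin(pmax(image, q[1]), q[2])
  rng <- range(img)
  if (rng[1] == rng[2]) {
    warning("constant image; returning zeros")
    return(matrix(0, nrow(image), ncol(image)))
  }
  (img - rng[1]) / (rng[2] - rng[1])
}

#' Encode subpixel spot coordinates as training targets
#'
#' Produces the three target images the detection model is trained on:
#' a one-hot classification image (one positive pixel per spot, at the
#' nearest pixel under round-half-away-from-zero), two regression images
#' holding the signed offset (spot minus pixel, pixels) to the nearest spot
#' per axis, and a validity mask restricting the regression loss to pixels
#' within `regressionRadius` (Euclidean) of a spot.
#'
#' @param spots data.frame with `row`, `col` (subpixel, 1-based) or a
#'   2-column matrix; may be empty.
#' @param shape `c(H, W)`.
#' @param regressionRadius neighborhood radius, pixels.
#' @return list of class `"TrainingTargets"`: `classification`, `dy`, `dx`,
#'   `mask` (all `H x W`; mask is logical).
#' @examples
#' t <- makeTargets(data.frame(row = 5.3, col = 7.8), c(16, 16))
#' which(t$classification == 1, arr.ind = TRUE)  # pixel (5, 8)
#' @export
makeTargets <- function(spots, shape, regressionRadius = 2) {
  H <- shape[1]; W <- shape[2]
  spots <- as.data.frame(spots)
  cls <- matrix(0, H, W); dy <- matrix(0, H, W); dx <- matrix(0, H, W)
  d2best <- matrix(Inf, H, W)
  if (nrow(spots) > 0) {
    .stopifnot2(all(spots$row >= 0.5 & spots$row <= H + 0.5 &
                    spots$col >= 0.5 & spots$col <= W + 0.5),
                "spots outside image bounds")
    pr <- pmin(pmax(roundHalfAway(spots$row), 1), H)
    pc <- pmin(pmax(roundHalfAway(spots$col), 1), W)
    if (anyDuplicated(cbind(pr, pc)))
      warning("multiple spots round to one pixel; classification keeps one positive")
    cls[cbind(pr, pc)] <- 1
    rad <- regressionRadius
    for (s in seq_len(nrow(spots))) {
      r0 <- spots$row[s]; c0 <- spots$col[s]
      rs <- max(1, floor(r0 - rad)):min(H, ceiling(r0 + rad))
      cs <- max(1, floor(c0 - rad)):min(W, ceiling(c0 + rad))
      d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
      sel <- d2 <= rad^2 & d2 < d2best[rs, cs, drop = FALSE]
      if (!any(sel)) next
      idx <- which(sel, arr.ind = TRUE)
      gi <- cbind(rs[idx[, 1]], cs[idx[, 2]])
      d2best[gi] <- d2[idx]
      dy[gi] <- r0 - gi[, 1]
      dx[gi] <- c0 - gi[, 2]
    }
  }
  structure(list(classification = cls, dy = dy, dx = dx,
                 mask = is.finite(d2best)),
            class = "TrainingTargets")
}

#' Build the fully convolutional spot detection model
#'
#' A stack of `(receptiveField - 1) / 2` blocks of 3x3 convolution (stride 1,
#' zero same-padding), batch normalization and ReLU, followed by two 1x1
#' heads: a one-channel classification head (spot-probability logit) and a
#' two-channel regression head (row/column subpixel offsets). The network is
#' translation equivariant, runs on any input at least as large as the
#' receptive field, and its effective receptive field equals
#' `receptiveField` exactly (each 3x3 layer adds 2 pixels).
#'
#' @param receptiveField odd integer >= 3 (default 13).
#' @param nFilters filters per convolution layer (default 8: trains in
#'   minutes on one CPU at desk scale; raise for more complex data).
#' @param seed integer seed for weight initialization (He normal).
#' @return a [SpotNet-class].
#' @export
buildSpotNet <- function(receptiveField = 13, nFilters = 8, seed = NULL) {
  .stopifnot2(receptiveField >= 3 && receptiveField %% 2 == 1,
              "receptiveField must be odd and >= 3")
  if (!is.null(seed)) set.seed(seed)
  depth <- (receptiveField - 1L) / 2L
  new("SpotNet",
      config = list(receptiveField = as.integer(receptiveField),
                    nFilters = as.integer(nFilters), depth = as.integer(depth)),
      params = .initParams(depth, nFilters),
      history = data.frame(), trained = FALSE)
}

setMethod("show", "SpotNet", function(object) {
  cat(sprintf("SpotNet: receptive field %d (%d conv layers x %d filters), %s\n",
              object@config$receptiveField, object@config$depth,
              object@config$nFilters,
              if (object@trained) sprintf("trained (%d epochs)", nrow(object@history))
              else "untrained"))
})

#' Predict pixel-wise spot probability and subpixel offsets
#'
#' Runs the model in inference mode (batch-norm running statistics) on one
#' image.
#'
#' @param net a [SpotNet-class].
#' @param image 2-D numeric matrix (preprocess with [preprocessImage()]).
#' @return a [SpotPrediction-class].
#' @export
predictSpotNet <- function(net, image) {
  .stopifnot2(is.matrix(image), "image must be a matrix")
  H <- nrow(image); W <- ncol(image)
  .stopifnot2(min(H, W) >= net@config$receptiveField,
              "image smaller than the receptive field")
  fwd <- .netForward(net@params, matrix(as.vector(image), ncol = 1), H, W, 1L,
                     training = FALSE)
  new("SpotPrediction",
      probability = matrix(.logistic(fwd$cls), H, W),
      dy = matrix(fwd$reg[, 1], H, W),
      dx = matrix(fwd$reg[, 2], H, W))
}

#' Classification + regression loss
#'
#' Total loss = weighted binary cross entropy over all pixels (positive
#' class upweighted by the background/spot pixel ratio, capped at
#' `posWeightCap`) plus mean squared error of the regression images
#' restricted to the validity mask. An empty mask contributes 0.
#'
#' @param pred a [SpotPrediction-class] (probabilities in \[0, 1\]).
#' @param targets a `"TrainingTargets"` list from [makeTargets()].
#' @param posWeight positive-class weight; `NULL` derives it from the target.
#' @param posWeightCap cap on the derived weight.
#' @return list `total`, `classification`, `regression`, `posWeight`.
#' @export
spotNetLoss <- function(pred, targets, posWeight = NULL, posWeightCap = 100) {
  p <- pmin(pmax(as.vector(pred@probability), 1e-7), 1 - 1e-7)
  y <- as.vector(targets$classification)
  if (is.null(posWeight)) {
    nPos <- sum(y); nNeg <- length(y) - nPos
    posWeight <- if (nPos > 0) min(nNeg / nPos, posWeightCap) else 1
  }
  w <- ifelse(y == 1, posWeight, 1)
  ce <- -sum(w * (y * log(p) + (1 - y) * log1p(-p))) / sum(w)
  m <- as.vector(targets$mask)
  nm <- sum(m)
  mse <- if (nm > 0) {
    sum(m * ((as.vector(pred@dy) - as.vector(targets$dy))^2 +
             (as.vector(pred@dx) - as.vector(targets$dx))^2)) / (2 * nm)
  } else 0
  list(total = ce + mse, classification = ce, regression = mse,
       posWeight = posWeight)
}

## loss + gradients on a batch in flat form (vectors over H*W*B pixels);
## cls is the logit column, reg the two offset columns
.batchLossGrad <- function(cls, reg, y, tdy, tdx, mask, posWeightCap = 100) {
  p <- .logistic(cls)
  nPos <- sum(y); nNeg <- length(y) - nPos
  pw <- if (nPos > 0) min(nNeg / nPos, posWeightCap) else 1
  w <- ifelse(y == 1, pw, 1)
  sw <- sum(w)
  pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ce <- -sum(w * (y * log(pc) + (1 - y) * log1p(-pc))) / sw
  dCls <- matrix(w * (p - y) / sw, ncol = 1)
  nm <- sum(mask)
  if (nm > 0) {
    e1 <- mask * (reg[, 1] - tdy); e2 <- mask * (reg[, 2] - tdx)
    mse <- sum(e1^2 + e2^2) / (2 * nm)
    dReg <- cbind(e1, e2) / nm
  } else {
    mse <- 0
    dReg <- matrix(0, length(y), 2)
  }
  list(ce = ce, mse = mse, dCls = dCls, dReg = dReg)
}

## bilinear-resampled affine augmentation of an image and its spot list;
## the map is flip -> rotate -> scale about the image center
.affineAugment <- function(image, spots, angle, flipH, flipV, scale) {
  H <- nrow(image); W <- ncol(image)
  ctr <- c((H + 1) / 2, (W + 1) / 2)
  th <- angle * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  F <- diag(c(if (flipV) -1 else 1, if (flipH) -1 else 1))
  M <- scale * R %*% F
  Minv <- solve(M)
  gr <- as.vector(row(image)); gc <- as.vector(col(image))
  src <- Minv %*% rbind(gr - ctr[1], gc - ctr[2])
  sr <- src[1, ] + ctr[1]; sc <- src[2, ] + ctr[2]
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  ok <- r0 >= 1 & r0 <= H - 1 & c0 >= 1 & c0 <= W - 1
  fill <- stats::median(image)
  out <- rep(fill, H * W)
  i <- which(ok)
  i00 <- cbind(r0[i], c0[i]); i10 <- cbind(r0[i] + 1, c0[i])
  i01 <- cbind(r0[i], c0[i] + 1); i11 <- cbind(r0[i] + 1, c0[i] + 1)
  out[i] <- image[i00] * (1 - fr[i]) * (1 - fc[i]) +
            image[i10] * fr[i] * (1 - fc[i]) +
            image[i01] * (1 - fr[i]) * fc[i] +
            image[i11] * fr[i] * fc[i]
  newSpots <- spots
  if (nrow(spots) > 0) {
    q <- M %*% rbind(spots$row - ctr[1], spots$col - ctr[2])
    newSpots <- data.frame(row = q[1, ] + ctr[1], col = q[2, ] + ctr[2])
    keep <- newSpots$row >= 1 & newSpots$row <= H &
            newSpots$col >= 1 & newSpots$col <= W
    newSpots <- newSpots[keep, , drop = FALSE]
  }
  list(image = matrix(out, H, W), spots = newSpots)
}

#' Train the spot detection model
#'
#' Stochastic gradient descent with Nesterov momentum (defaults: learning
#' rate 0.01, momentum 0.9) on the weighted cross-entropy plus masked
#' regression loss. The data are split 90/10 into training and validation
#' sets by seed; per-image augmentation (rotation 0-180 degrees, horizontal
#' and vertical flips, scaling 0.8-1.2x) is resampled every epoch. Training
#' is deterministic given the seed.
#'
#' @param net a [SpotNet-class].
#' @param images list of equal-shaped 2-D matrices (preprocessed).
#' @param spots list of data.frames with subpixel `row`, `col` per image.
#' @param epochs,batchSize training schedule (`epochs = 0` returns the model
#'   unchanged).
#' @param lr,momentum SGD hyperparameters.
#' @param valFraction validation fraction in (0, 1).
#' @param augment logical, apply geometric augmentation.
#' @param regressionRadius radius (pixels) of the regression-loss
#'   neighborhood around each spot.
#' @param posWeightCap cap on the per-batch positive-class weight.
#' @param seed integer seed controlling split, shuffling and augmentation.
#' @param verbose print per-epoch losses.
#' @return the trained [SpotNet-class] with a filled `history`.
#' @export
trainSpotNet <- function(net, images, spots, epochs = 20, batchSize = 8,
                         lr = 0.01, momentum = 0.9, valFraction = 0.1,
                         augment = TRUE, regressionRadius = 2,
                         posWeightCap = 100, seed = 1, verbose = FALSE) {
  n <- length(images)
  .stopifnot2(n >= 2 && length(spots) == n, "need >= 2 images with matching spot lists")
  .stopifnot2(valFraction > 0 && valFraction < 1, "valFraction must be in (0, 1)")
  if (epochs == 0) return(net)
  dims <- vapply(images, dim, integer(2))
  .stopifnot2(all(dims == dims[, 1]), "all images must share one shape")
  H <- dims[1, 1]; W <- dims[2, 1]
  set.seed(seed)
  nVal <- max(1, round(valFraction * n))
  valIdx <- sample.int(n, nVal)
  trainIdx <- setdiff(seq_len(n), valIdx)
  valTargets <- lapply(valIdx, function(i)
    makeTargets(spots[[i]], c(H, W), regressionRadius))

  params <- net@params
  vel <- list(layers = vector("list", net@config$depth),
              headCls = NULL, headReg = NULL)
  hist <- data.frame()
  for (ep in seq_len(epochs)) {
    ord <- sample(trainIdx)
    starts <- seq(1, length(ord), by = batchSize)
    epLoss <- c(0, 0); nb <- 0
    for (s0 in starts) {
      bi <- ord[s0:min(s0 + batchSize - 1, length(ord))]
      B <- length(bi)
      A <- matrix(0, H * W * B, 1)
      y <- tdy <- tdx <- msk <- numeric(H * W * B)
      for (k in seq_along(bi)) {
        img <- images[[bi[k]]]; sp <- spots[[bi[k]]]
        if (augment) {
          a <- .affineAugment(img, sp, runif(1, 0, 180), runif(1) < 0.5,
                              runif(1) < 0.5, runif(1, 0.8, 1.2))
          img <- a$image; sp <- a$spots
        }
        tg <- makeTargets(sp, c(H, W), regressionRadius)
        sl <- ((k - 1) * H * W + 1):(k * H * W)
        A[sl, 1] <- as.vector(img)
        y[sl] <- as.vector(tg$classification)
        tdy[sl] <- as.vector(tg$dy); tdx[sl] <- as.vector(tg$dx)
        msk[sl] <- as.vector(tg$mask)
      }
      fwd <- .netForward(params, A, H, W, B, training = TRUE)
      lg <- .batchLossGrad(fwd$cls[, 1], fwd$reg, y, tdy, tdx, msk, posWeightCap)
      if (!is.finite(lg$ce + lg$mse))
        stop(sprintf("training diverged (NaN loss) at epoch %d", ep), call. = FALSE)
      bk <- .netBackward(params, fwd, lg$dCls, lg$dReg, H, W, B)
      params <- bk$params
      up <- .sgdUpdate(params, bk$grads, vel, lr, momentum)
      params <- up$params; vel <- up$vel
      epLoss <- epLoss + c(lg$ce, lg$mse); nb <- nb + 1
    }
    ## validation in inference mode
    vl <- c(0, 0)
    for (k in seq_along(valIdx)) {
      img <- images[[valIdx[k]]]
      fwd <- .netForward(params, matrix(as.vector(img), ncol = 1), H, W, 1L, FALSE)
      tg <- valTargets[[k]]
      lg <- .batchLossGrad(fwd$cls[, 1], fwd$reg, as.vector(tg$classification),
                           as.vector(tg$dy), as.vector(tg$dx),
                           as.vector(tg$mask), posWeightCap)
      vl <- vl + c(lg$ce, lg$mse)
    }
    vl <- vl / length(valIdx)
    row <- data.frame(epoch = ep, trainCls = epLoss[1] / nb,
                      trainReg = epLoss[2] / nb,
                      trainLoss = sum(epLoss) / nb,
                      valCls = vl[1], valReg = vl[2], valLoss = sum(vl))
    hist <- rbind(hist, row)
    if (verbose)
      message(sprintf("epoch %d: train %.4f val %.4f", ep, row$trainLoss, row$valLoss))
  }
  net@params <- params
  net@history <- hist
  net@trained <- TRUE
  net
}

#' Convert model predictions into a subpixel spot list
#'
#' Local maxima of the probability image strictly above `threshold` are
#' found by maximum filtering with `minDistance` spacing; each maximum's
#' coordinate is its pixel location plus the regression offsets predicted at
#' that pixel.
#'
#' @param pred a [SpotPrediction-class].
#' @param threshold probability threshold (default 0.95).
#' @param minDistance half-width of the maximum filter window, pixels.
#' @return data.frame with `row`, `col` (subpixel), `score`, `annotator`.
#' @export
postprocessPrediction <- function(pred, threshold = 0.95, minDistance = 1) {
  pk <- .localMaxima(pred@probability, threshold, minDistance)
  if (nrow(pk) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), score = numeric(0),
                      annotator = character(0)))
  }
  idx <- cbind(pk$row, pk$col)
  data.frame(row = pk$row + pred@dy[idx], col = pk$col + pred@dx[idx],
             score = pk$score, annotator = "spotnet")
}
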