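## Internal neural-network primitives for the spot detection model.
##
## Activations for a batch are stored as a (H*W*B) x C matrix whose rows are
## ordered row-fastest, then column, then batch image. 3x3 same-padding
## convolutions run in compiled code (src/conv3x3.cpp) as nine
## shifted-window BLAS products; 1x1 head convolutions are plain matrix
## products. Batch normalization keeps running statistics for inference.
## Convolution layers carry no bias: batch norm absorbs it.

#' @useDynLib SpotSuite, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## column-wise affine: X * a[col] + b[col], without sweep()'s aperm overhead
.colAffine <- function(X, a, b) {
  N <- nrow(X)
  X * rep(a, each = N) + rep(b, each = N)
}

## full forward pass; training=TRUE uses batch statistics and keeps caches
.netForward <- function(params, A, H, W, B, training = FALSE) {
  caches <- if (training) vector("list", length(params$layers)) else NULL
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    Z <- .convForwardCpp(A, ly$W, H, W, B)
    if (training) {
      bn <- .bnReluFwdCpp(Z, ly$gamma, ly$beta, 1e-5)
      caches[[l]] <- list(Ain = A, bn = bn)
      A <- bn$out
    } else {
      A <- .bnReluInferCpp(Z, ly$gamma, ly$beta, ly$runMean, ly$runVar, 1e-5)
    }
  }
  cls <- A %*% params$headCls$W + params$headCls$b
  reg <- .colAffine(A %*% params$headReg$W, c(1, 1), params$headReg$b)
  list(feat = A, cls = cls, reg = reg, caches = caches)
}

## backward pass; returns gradients mirroring the parameter layout and the
## parameter list with updated batch-norm running statistics
.netBackward <- function(params, fwd, dCls, dReg, H, W, B, bnMomentum = 0.9) {
  g <- list(layers = vector("list", length(params$layers)))
  g$headCls <- list(W = crossprod(fwd$feat, dCls), b = sum(dCls))
  g$headReg <- list(W = crossprod(fwd$feat, dReg), b = colSums(dReg))
  dA <- dCls %*% t(params$headCls$W) + dReg %*% t(params$headReg$W)
  for (l in rev(seq_along(params$layers))) {
    ly <- params$layers[[l]]
    ca <- fwd$caches[[l]]
    bb <- .bnReluBwdCpp(dA, ca$bn$out, ca$bn$xhat, ly$gamma, ca$bn$invstd)
    cv <- .convBackwardCpp(ca$Ain, ly$W, bb$dZ, H, W, B, l > 1)
    g$layers[[l]] <- list(W = cv$dW, gamma = as.vector(bb$dGamma),
                          beta = as.vector(bb$dBeta))
    if (l > 1) dA <- cv$dA
    params$layers[[l]]$runMean <- bnMomentum * ly$runMean +
      (1 - bnMomentum) * as.vector(ca$bn$mean)
    params$layers[[l]]$runVar <- bnMomentum * ly$runVar +
      (1 - bnMomentum) * as.vector(ca$bn$var)
  }
  list(grads = g, params = params)
}

.initParams <- function(depth, nFilters) {
  layers <- vector("list", depth)
  cin <- 1L
  for (l in seq_len(depth)) {
    fanIn <- 9L * cin
    layers[[l]] <- list(
      W = matrix(rnorm(fanIn * nFilters, 0, sqrt(2 / fanIn)), fanIn, nFilters),
      gamma = rep(1, nFilters), beta = numeric(nFilters),
      runMean = numeric(nFilters), runVar = rep(1, nFilters))
    cin <- nFilters
  }
  list(layers = layers,
       headCls = list(W = matrix(rnorm(nFilters, 0, sqrt(1 / nFilters))), b = 0),
       headReg = list(W = matrix(rnorm(2 * nFilters, 0, sqrt(1 / nFilters)),
                                 nFilters, 2), b = numeric(2)))
}

## elementwise SGD with Nesterov momentum over the nested parameter list;
## batch-norm running stats are not touched
.sgdUpdate <- function(params, grads, vel, lr, momentum) {
  walk <- function(p, g, v) {
    if (is.list(p)) {
      out <- Map(walk, p, g, v %||% vector("list", length(p)))
      return(list(p = lapply(out, `[[`, "p"), v = lapply(out, `[[`, "v")))
    }
    if (is.null(v)) v <- p * 0
    vNew <- momentum * v - lr * g
    list(p = p + momentum * vNew - lr * g, v = vNew)
  }
  trainNames <- c("W", "gamma", "beta")
  for (l in seq_along(params$layers)) {
    ly <- params$layers[[l]]
    keep <- trainNames[trainNames %in% names(ly)]
    o <- walk(ly[keep], grads$layers[[l]][keep], vel$layers[[l]])
    params$layers[[l]][keep] <- o$p
    vel$layers[[l]] <- o$v
  }
  for (h in c("headCls", "headReg")) {
    o <- walk(params[[h]], grads[[h]], vel[[h]])
    params[[h]] <- o$p
    vel[[h]] <- o$v
  }
  list(params = params, vel = vel)
}
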