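#' @import methods
#' @importFrom stats rnorm runif rbeta rbinom optim setNames quantile sd
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Deterministic nearest-integer rounding used to place subpixel spot
#' coordinates on the pixel grid: values ending in .5 round away from zero,
#' unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

.stopifnot2 <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

## maximum over the window EXCLUDING the center pixel
.neighborMax <- function(img, k) {
  H <- nrow(img); W <- ncol(img)
  pad <- matrix(-Inf, H + 2 * k, W + 2 * k)
  pad[(k + 1):(k + H), (k + 1):(k + W)] <- img
  out <- matrix(-Inf, H, W)
  for (di in 0:(2 * k)) {
    rows <- (1 + di):(H + di)
    sub <- pad[rows, , drop = FALSE]
    for (dj in 0:(2 * k)) {
      if (di == k && dj == k) next
      out <- pmax(out, sub[, (1 + dj):(W + dj), drop = FALSE])
    }
  }
  out
}

## local maxima strictly above `threshold`; a pixel is a maximum when it
## strictly exceeds every other pixel in a window of half-width
## `minDistance` (plateau ties are suppressed, so a constant image has none)
.localMaxima <- function(img, threshold, minDistance = 1) {
  mf <- .neighborMax(img, max(1L, as.integer(minDistance)))
  idx <- which(img > mf & img > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(row = numeric(0), col = numeric(0), score = numeric(0)))
  }
  data.frame(row = idx[, 1], col = idx[, 2], score = img[idx])
}

## render sum of isotropic 2-D Gaussians onto an H x W grid
## (pixel centers at integer coordinates, 1-based)
.renderGaussians <- function(shape, rows, cols, amplitudes, sigmas) {
  H <- shape[1]; W <- shape[2]
  img <- matrix(0, H, W)
  if (length(rows) == 0) return(img)
  r <- seq_len(H); c <- seq_len(W)
  for (s in seq_along(rows)) {
    dr2 <- (r - rows[s])^2
    dc2 <- (c - cols[s])^2
    img <- img + amplitudes[s] *
      outer(exp(-dr2 / (2 * sigmas[s]^2)), exp(-dc2 / (2 * sigmas[s]^2)))
  }
  img
}

## separable Gaussian blur with reflective borders
.gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- max(1L, ceiling(3 * sigma))
  x <- (-k):k
  w <- exp(-x^2 / (2 * sigma^2)); w <- w / sum(w)
  H <- nrow(img); W <- ncol(img)
  refl <- function(i, n) { # reflect indices 101-style
    i <- abs(i - 1L) %% (2L * (n - 1L))
    pmin(i, 2L * (n - 1L) - i) + 1L
  }
  out <- matrix(0, H, W)
  for (t in seq_along(x)) out <- out + w[t] * img[refl(seq_len(H) + x[t], H), , drop = FALSE]
  out2 <- matrix(0, H, W)
  for (t in seq_along(x)) out2 <- out2 + w[t] * out[, refl(seq_len(W) + x[t], W), drop = FALSE]
  out2
}

.logistic <- function(x) 1 / (1 + exp(-x))
.logit <- function(p) log(p) - log1p(-p)

.rowLogSumExp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

## truncated-normal sampling by rejection (truncation well inside the bulk here)
.rnormTrunc <- function(n, mean, sd, lower) {
  if (sd < 0) stop("standard deviation must be >= 0", call. = FALSE)
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
    guard <- guard + 1L
    if (guard > 1000L) stop("degenerate truncated-normal parameters", call. = FALSE)
  }
  out
}
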