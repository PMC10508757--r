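#' Relaxed Bernoulli (binary Concrete) density
#'
#' Density on the open interval (0, 1) with probability parameter `alpha`
#' and temperature `lambda`:
#' `f(x) = lambda * r * x^(-lambda-1) * (1-x)^(-lambda-1) /
#'         (r * x^(-lambda) + (1-x)^(-lambda))^2`, `r = alpha / (1 - alpha)`.
#' Low temperatures concentrate mass near 0 and 1, recovering the Bernoulli
#' in the limit.
#'
#' @param x values strictly inside (0, 1) (clamped to
#'   `[1e-4, 1 - 1e-4]`).
#' @param alpha probability parameter in (0, 1).
#' @param lambda temperature > 0.
#' @param log return the log density.
#' @return numeric vector of (log) densities.
#' @export
dRelaxedBernoulli <- function(x, alpha, lambda, log = FALSE) {
  .stopifnot2(all(alpha > 0 & alpha < 1), "alpha must lie in (0, 1)")
  .stopifnot2(all(lambda > 0), "lambda must be > 0")
  x <- pmin(pmax(x, 1e-4), 1 - 1e-4)
  eta <- .logit(alpha)
  lx <- base::log(x); l1x <- log1p(-x)
  lu <- eta - lambda * lx
  lv <- -lambda * l1x
  lse <- pmax(lu, lv) + log1p(exp(-abs(lu - lv)))
  out <- base::log(lambda) + eta - (lambda + 1) * (lx + l1x) - 2 * lse
  if (log) out else exp(out)
}

## per-bit log densities and their gradients wrt logit(alpha) and log(lambda)
.rbParts <- function(x, eta, lambda) {
  lx <- log(x); l1x <- log1p(-x)
  lu <- sweep(-lambda * lx, 2, eta, "+")
  lv <- -lambda * l1x
  lse <- pmax(lu, lv) + log1p(exp(-abs(lu - lv)))
  w <- .logistic(lu - lv)              # u / (u + v)
  logf <- sweep(-(lambda + 1) * (lx + l1x) - 2 * lse, 2, eta + log(lambda), "+")
  dEta <- 1 - 2 * w
  dLogLam <- 1 - lambda * (lx + l1x) + 2 * lambda * (w * lx + (1 - w) * l1x)
  list(logf = logf, dEta = dEta, dLogLam = dLogLam)
}

#' Select decodable pixels from a probability stack
#'
#' Pixels whose maximum spot probability across all rounds and channels
#' exceeds `threshold` are returned with their full trace over the
#' `nRounds * nChannels` bits.
#'
#' @param stack numeric array `H x W x (R*C)` of per-round/channel spot
#'   probability images in \[0, 1\], bit order matching the codebook
#'   (round-major).
#' @param threshold max-projection threshold (default 0.01, strict).
#' @return list of class `"PixelTraces"`: `coords` (data.frame `row`,
#'   `col`), `traces` (n x bits matrix), `shape`.
#' @export
selectDecodablePixels <- function(stack, threshold = 0.01) {
  .stopifnot2(length(dim(stack)) == 3, "stack must be H x W x bits")
  .stopifnot2(all(stack >= 0 & stack <= 1), "stack values must lie in [0, 1]")
  d <- dim(stack)
  flat <- matrix(stack, d[1] * d[2], d[3])
  proj <- do.call(pmax, as.data.frame(flat))
  sel <- which(proj > threshold)
  coords <- data.frame(row = ((sel - 1) %% d[1]) + 1,
                       col = ((sel - 1) %/% d[1]) + 1)
  structure(list(coords = coords,
                 traces = flat[sel, , drop = FALSE],
                 shape = d[1:2]),
            class = "PixelTraces")
}

.tracesOf <- function(x) {
  if (inherits(x, "PixelTraces")) x$traces
  else if (inherits(x, "SimulatedBarcodeSet")) x$traces
  else as.matrix(x)
}

#' Fit the barcode mixture model
#'
#' Fits the two-component-per-bit generative model of barcode traces: each
#' of the `2 * R * C` mixture pieces is a "spot" or "background"
#' distribution for one round/channel, assembled into one component per
#' codebook row (including the background barcode) by picking the spot
#' distribution at on bits and the background distribution at off bits.
#' Bits are independent; parameters are shared across genes; the latent gene
#' identity has a uniform categorical prior.
#'
#' For the default relaxed-Bernoulli family the per-bit probability
#' parameters (via their logits, which the codebook ties to the spot or
#' background state) and the single shared temperature are fit by
#' stochastic gradient-based variational inference: the discrete latent is
#' marginalized exactly, so the evidence lower bound coincides with the log
#' evidence, which Adam maximizes over minibatches. The `bernoulli` family
#' binarizes traces at 0.5 and the `gaussian` family models each bit with a
#' normal distribution; both are fit by EM. All fits are deterministic given
#' the seed.
#'
#' @param traces a `"PixelTraces"`, `"SimulatedBarcodeSet"` or numeric
#'   matrix (n x bits) of values in (0, 1).
#' @param codebook a [Codebook-class] (background barcode included).
#' @param family one of `"relaxed_bernoulli"`, `"bernoulli"`, `"gaussian"`.
#' @param steps,lr,minibatch optimizer schedule for the relaxed family
#'   (Adam; `minibatch = NULL` uses full batches), or EM iteration count for
#'   the closed-form families (`steps`, capped at 200).
#' @param seed integer seed (minibatch sampling).
#' @return list of class `"BarcodeMixture"`: `family`, `alphaSpot`,
#'   `alphaBg`, `temperature` (relaxed family), `muSpot`/`sdSpot`/
#'   `muBg`/`sdBg` (gaussian), `logLik` (mean per-trace log evidence trace).
#'   A label-switching guard enforces `alphaSpot > alphaBg` (and
#'   `muSpot > muBg`) per bit after fitting.
#' @export
fitBarcodeMixture <- function(traces, codebook, family = c("relaxed_bernoulli",
                                                           "bernoulli", "gaussian"),
                              steps = 1000, lr = 0.01, minibatch = 1024,
                              seed = 1) {
  family <- match.arg(family)
  X <- pmin(pmax(.tracesOf(traces), 1e-4), 1 - 1e-4)
  B <- barcodeMatrix(codebook, withBackground = TRUE)
  .stopifnot2(ncol(X) == ncol(B), "trace width must equal codebook bits")
  n <- nrow(X); nb <- ncol(X)
  .stopifnot2(n >= 1, "no traces to fit")
  if (!is.null(seed)) set.seed(seed)

  if (family == "relaxed_bernoulli") {
    theta <- c(rep(.logit(0.8), nb), rep(.logit(0.2), nb), 0)   # etaS, etaB, log lambda
    m <- v <- numeric(length(theta)); b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    llTrace <- numeric(0)
    fullLL <- function(th) {
      ps <- .rbParts(X, th[seq_len(nb)], exp(th[2 * nb + 1]))
      pb <- .rbParts(X, th[nb + seq_len(nb)], exp(th[2 * nb + 1]))
      ll <- ps$logf %*% t(B) + pb$logf %*% t(1 - B) - log(nrow(B))
      mean(.rowLogSumExp(ll))
    }
    for (t in seq_len(steps)) {
      idx <- if (is.null(minibatch) || minibatch >= n) seq_len(n)
             else sample.int(n, minibatch)
      Xb <- X[idx, , drop = FALSE]
      lam <- exp(theta[2 * nb + 1])
      ps <- .rbParts(Xb, theta[seq_len(nb)], lam)
      pb <- .rbParts(Xb, theta[nb + seq_len(nb)], lam)
      ll <- ps$logf %*% t(B) + pb$logf %*% t(1 - B)
      r <- exp(ll - .rowLogSumExp(ll))                  # responsibilities
      wS <- r %*% B                                     # weight on spot state
      gEtaS <- colSums(wS * ps$dEta) / length(idx)
      gEtaB <- colSums((1 - wS) * pb$dEta) / length(idx)
      gLam <- sum(wS * ps$dLogLam + (1 - wS) * pb$dLogLam) / length(idx)
      g <- c(gEtaS, gEtaB, gLam)
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      theta <- theta + lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + epsA)
      if (t %% 100 == 0 || t == steps) llTrace <- c(llTrace, fullLL(theta))
      if (!all(is.finite(theta))) stop("mixture fit diverged (non-finite parameters)")
    }
    aS <- .logistic(theta[seq_len(nb)]); aB <- .logistic(theta[nb + seq_len(nb)])
    sw <- aS < aB                                       # label-switching guard
    if (any(sw)) { tmp <- aS[sw]; aS[sw] <- aB[sw]; aB[sw] <- tmp }
    out <- list(family = family, alphaSpot = aS, alphaBg = aB,
                temperature = exp(theta[2 * nb + 1]), logLik = llTrace)
  } else if (family == "bernoulli") {
    Xb <- (X > 0.5) * 1
    aS <- rep(0.8, nb); aB <- rep(0.2, nb)
    llTrace <- numeric(0)
    for (it in seq_len(min(steps, 200))) {
      lS <- sweep(Xb, 2, log(aS), "*") + sweep(1 - Xb, 2, log1p(-aS), "*")
      lB <- sweep(Xb, 2, log(aB), "*") + sweep(1 - Xb, 2, log1p(-aB), "*")
      ll <- lS %*% t(B) + lB %*% t(1 - B)
      r <- exp(ll - .rowLogSumExp(ll))
      wS <- r %*% B
      aS <- pmin(pmax(colSums(wS * Xb) / pmax(colSums(wS), 1e-12), 1e-4), 1 - 1e-4)
      aB <- pmin(pmax(colSums((1 - wS) * Xb) / pmax(colSums(1 - wS), 1e-12), 1e-4), 1 - 1e-4)
      llTrace <- c(llTrace, mean(.rowLogSumExp(ll - log(nrow(B)))))
    }
    sw <- aS < aB
    if (any(sw)) { tmp <- aS[sw]; aS[sw] <- aB[sw]; aB[sw] <- tmp }
    out <- list(family = family, alphaSpot = aS, alphaBg = aB,
                temperature = NA_real_, logLik = llTrace)
  } else {
    muS <- rep(0.8, nb); muB <- rep(0.2, nb); sdS <- sdB <- rep(0.2, nb)
    llTrace <- numeric(0)
    for (it in seq_len(min(steps, 200))) {
      lS <- -0.5 * sweep(sweep(X, 2, muS, "-")^2, 2, sdS^2, "/") -
        matrix(log(sdS) + 0.5 * log(2 * pi), n, nb, byrow = TRUE)
      lB <- -0.5 * sweep(sweep(X, 2, muB, "-")^2, 2, sdB^2, "/") -
        matrix(log(sdB) + 0.5 * log(2 * pi), n, nb, byrow = TRUE)
      ll <- lS %*% t(B) + lB %*% t(1 - B)
      r <- exp(ll - .rowLogSumExp(ll))
      wS <- r %*% B
      nS <- pmax(colSums(wS), 1e-12); nB <- pmax(colSums(1 - wS), 1e-12)
      muS <- colSums(wS * X) / nS
      muB <- colSums((1 - wS) * X) / nB
      sdS <- pmax(sqrt(colSums(wS * sweep(X, 2, muS, "-")^2) / nS), 1e-3)
      sdB <- pmax(sqrt(colSums((1 - wS) * sweep(X, 2, muB, "-")^2) / nB), 1e-3)
      llTrace <- c(llTrace, mean(.rowLogSumExp(ll - log(nrow(B)))))
    }
    sw <- muS < muB
    if (any(sw)) {
      tmp <- muS[sw]; muS[sw] <- muB[sw]; muB[sw] <- tmp
      tmp <- sdS[sw]; sdS[sw] <- sdB[sw]; sdB[sw] <- tmp
    }
    out <- list(family = family, muSpot = muS, muBg = muB, sdSpot = sdS,
                sdBg = sdB, temperature = NA_real_, logLik = llTrace)
  }
  if (!all(is.finite(unlist(out[!names(out) %in% "family"]))) &&
      family == "relaxed_bernoulli")
    stop("mixture fit produced non-finite parameters")
  class(out) <- "BarcodeMixture"
  out
}

#' @export
print.BarcodeMixture <- function(x, ...) {
  cat(sprintf("BarcodeMixture (%s): %d bits\n", x$family,
              length(x$alphaSpot %||% x$muSpot)))
  if (x$family == "gaussian")
    cat(sprintf("  mean spot mu %.3f / bg mu %.3f\n", mean(x$muSpot), mean(x$muBg)))
  else
    cat(sprintf("  mean alpha spot %.3f / bg %.3f, temperature %.3f\n",
                mean(x$alphaSpot), mean(x$alphaBg), x$temperature))
  invisible(x)
}

## per-bit spot/background log-density matrices for a fitted mixture
.bitLogDens <- function(X, params) {
  nb <- ncol(X)
  if (params$family == "relaxed_bernoulli") {
    lS <- .rbParts(X, .logit(params$alphaSpot), params$temperature)$logf
    lB <- .rbParts(X, .logit(params$alphaBg), params$temperature)$logf
  } else if (params$family == "bernoulli") {
    Xb <- (X > 0.5) * 1
    lS <- sweep(Xb, 2, log(params$alphaSpot), "*") +
      sweep(1 - Xb, 2, log1p(-params$alphaSpot), "*")
    lB <- sweep(Xb, 2, log(params$alphaBg), "*") +
      sweep(1 - Xb, 2, log1p(-params$alphaBg), "*")
  } else {
    n <- nrow(X)
    lS <- -0.5 * sweep(sweep(X, 2, params$muSpot, "-")^2, 2, params$sdSpot^2, "/") -
      matrix(log(params$sdSpot) + 0.5 * log(2 * pi), n, nb, byrow = TRUE)
    lB <- -0.5 * sweep(sweep(X, 2, params$muBg, "-")^2, 2, params$sdBg^2, "/") -
      matrix(log(params$sdBg) + 0.5 * log(2 * pi), n, nb, byrow = TRUE)
  }
  list(lS = lS, lB = lB)
}

#' Assign barcodes to traces
#'
#' Computes, per trace, the posterior probability of every codebook row
#' (uniform prior, per-bit independence: spot density at on bits, background
#' density at off bits) and assigns the maximum a posteriori row. Rows whose
#' posterior falls below `probThreshold` become `"unknown"`; the all-zero
#' barcode yields `"background"`.
#'
#' @param traces a `"PixelTraces"`, `"SimulatedBarcodeSet"` or matrix.
#' @param params a fitted `"BarcodeMixture"`.
#' @param codebook a [Codebook-class].
#' @param probThreshold assignment threshold (default 0.95).
#' @return data.frame with `row`/`col` (when available, else NA), `gene`,
#'   `geneIndex` (argmax codebook row), `probability`, `status`; the full
#'   posterior matrix is attached as attribute `"posterior"`.
#' @export
assignBarcodes <- function(traces, params, codebook, probThreshold = 0.95) {
  X <- pmin(pmax(.tracesOf(traces), 1e-4), 1 - 1e-4)
  B <- barcodeMatrix(codebook, withBackground = TRUE)
  ld <- .bitLogDens(X, params)
  ll <- ld$lS %*% t(B) + ld$lB %*% t(1 - B)
  post <- exp(ll - .rowLogSumExp(ll))
  gi <- max.col(post, ties.method = "first")
  prob <- post[cbind(seq_len(nrow(post)), gi)]
  bgRow <- nrow(B)
  status <- ifelse(prob < probThreshold, "unknown",
                   ifelse(gi == bgRow, "background", "assigned"))
  coords <- if (inherits(traces, "PixelTraces")) traces$coords
            else data.frame(row = rep(NA_real_, nrow(X)), col = NA_real_)
  out <- data.frame(row = coords$row, col = coords$col,
                    gene = geneNames(codebook, TRUE)[gi], geneIndex = gi,
                    probability = prob, status = status)
  attr(out, "posterior") <- post
  out
}

## Hamming distances from binarized traces to every real-gene barcode
.hammingToGenes <- function(bin, B) {
  outer(rowSums(bin), rep(1, nrow(B))) +
    matrix(rowSums(B), nrow(bin), nrow(B), byrow = TRUE) -
    2 * bin %*% t(B)
}

## unique-minimum rescue rule: the candidate barcode, or 0 when the minimal
## distance exceeds maxDist or is tied
.uniqueMinRescue <- function(d, maxDist = 1) {
  apply(d, 1, function(di) {
    mn <- min(di)
    if (mn > maxDist || sum(di == mn) != 1) 0L else which.min(di)
  })
}

#' Error rescue of unassigned traces
#'
#' Traces assigned `"background"` or `"unknown"` are binarized at 0.5 and
#' compared to every real-gene barcode; when the minimal Hamming distance is
#' at most 1 and achieved by exactly one gene, the trace is reassigned to
#' that gene with status `"rescued_error"`. Ties are left untouched
#' (ambiguous).
#'
#' @param assignments data.frame from [assignBarcodes()].
#' @param traces the traces the assignments were computed from.
#' @param codebook a [Codebook-class].
#' @return the updated assignments.
#' @export
errorRescue <- function(assignments, traces, codebook) {
  X <- .tracesOf(traces)
  .stopifnot2(nrow(X) == nrow(assignments), "assignments/traces length mismatch")
  cand <- which(assignments$status %in% c("background", "unknown"))
  if (length(cand) == 0) return(assignments)
  B <- barcodeMatrix(codebook)
  bin <- (X[cand, , drop = FALSE] > 0.5) * 1
  hit <- .uniqueMinRescue(.hammingToGenes(bin, B), 1)
  ok <- hit > 0
  idx <- cand[ok]
  assignments$gene[idx] <- geneNames(codebook)[hit[ok]]
  assignments$geneIndex[idx] <- hit[ok]
  assignments$status[idx] <- "rescued_error"
  assignments
}

#' Mixed-barcode rescue of low-confidence traces
#'
#' Catches traces carrying two overlapping transcripts: for traces whose
#' maximum a posteriori gene is real but whose posterior fell below
#' `probThreshold`, the assigned barcode's bits are subtracted from the
#' binarized trace (clamped at 0). If the residual is within Hamming
#' distance 1 of exactly one other real gene, both transcripts are recorded
#' (the original row is promoted and a second row appended, both with status
#' `"rescued_mixed"`). `replace = TRUE` instead replaces the original gene
#' by the residual match.
#'
#' @inheritParams errorRescue
#' @param probThreshold confidence threshold below which mixing is suspected.
#' @param replace replace the original assignment rather than appending.
#' @return the updated assignments (possibly with appended rows).
#' @export
mixedRescue <- function(assignments, traces, codebook, probThreshold = 0.95,
                        replace = FALSE) {
  X <- .tracesOf(traces)
  .stopifnot2(nrow(X) == nrow(assignments), "assignments/traces length mismatch")
  B <- barcodeMatrix(codebook)
  nReal <- nrow(B)
  cand <- which(assignments$geneIndex <= nReal &
                assignments$probability < probThreshold &
                assignments$status %in% c("assigned", "unknown"))
  if (length(cand) == 0) return(assignments)
  bin <- (X[cand, , drop = FALSE] > 0.5) * 1
  resid <- pmax(bin - B[assignments$geneIndex[cand], , drop = FALSE], 0)
  d <- .hammingToGenes(resid, B)
  d[cbind(seq_along(cand), assignments$geneIndex[cand])] <- Inf  # exclude original
  hit <- .uniqueMinRescue(d, 1)
  hit[rowSums(resid) == 0] <- 0L                                  # nothing left over
  ok <- hit > 0
  if (!any(ok)) return(assignments)
  idx <- cand[ok]
  second <- assignments[idx, , drop = FALSE]
  second$gene <- geneNames(codebook)[hit[ok]]
  second$geneIndex <- hit[ok]
  second$status <- "rescued_mixed"
  if (replace) {
    assignments[idx, ] <- second
    return(assignments)
  }
  assignments$status[idx] <- "rescued_mixed"
  out <- rbind(assignments, second)
  rownames(out) <- NULL
  out
}

#' Mask items falling on bright background structures
#'
#' Min-max normalizes a background/autofluorescence image and removes every
#' item whose (rounded) pixel position lies where the normalized background
#' strictly exceeds `threshold`. A pre-computed logical mask of regions to
#' drop may be supplied instead of an image.
#'
#' @param items a data.frame with `row`/`col`, a `"PixelTraces"`, or a
#'   [DecodedSpots-class].
#' @param backgroundImage numeric matrix, or logical matrix (TRUE = drop).
#' @param threshold normalized-intensity threshold (default 0.5).
#' @return the filtered items, same type as the input.
#' @export
applyBackgroundMask <- function(items, backgroundImage, threshold = 0.5) {
  if (is.logical(backgroundImage)) {
    drop <- backgroundImage
  } else {
    rng <- range(backgroundImage)
    nb <- if (rng[1] == rng[2]) backgroundImage * 0
          else (backgroundImage - rng[1]) / (rng[2] - rng[1])
    drop <- nb > threshold
  }
  coords <- if (inherits(items, "PixelTraces")) items$coords
            else if (is(items, "DecodedSpots")) items@spots
            else items
  pr <- pmin(pmax(roundHalfAway(coords$row), 1), nrow(drop))
  pc <- pmin(pmax(roundHalfAway(coords$col), 1), ncol(drop))
  keep <- !drop[cbind(pr, pc)]
  if (inherits(items, "PixelTraces")) {
    items$coords <- items$coords[keep, , drop = FALSE]
    items$traces <- items$traces[keep, , drop = FALSE]
    items
  } else if (is(items, "DecodedSpots")) {
    s <- items@spots[keep, , drop = FALSE]
    rownames(s) <- NULL
    new("DecodedSpots", spots = s)
  } else items[keep, , drop = FALSE]
}

#' Extract decoded transcripts from per-pixel assignments
#'
#' Masks the max-projected probability image to the successfully decoded
#' pixels (status `assigned`, `rescued_error` or `rescued_mixed`), finds
#' local maxima within the mask by maximum filtering, and emits one
#' transcript per maximum carrying the gene assignment at that pixel.
#'
#' @param assignments per-pixel data.frame from [assignBarcodes()] (with
#'   valid `row`/`col`, possibly after rescues).
#' @param stack the `H x W x bits` probability stack.
#' @param minDistance half-width of the maximum filter window, pixels.
#' @return a [DecodedSpots-class].
#' @export
extractDecodedSpots <- function(assignments, stack, minDistance = 1) {
  d <- dim(stack)
  flat <- matrix(stack, d[1] * d[2], d[3])
  proj <- matrix(do.call(pmax, as.data.frame(flat)), d[1], d[2])
  decoded <- assignments[assignments$status %in%
                           c("assigned", "rescued_error", "rescued_mixed"), ,
                         drop = FALSE]
  emptyDf <- data.frame(row = numeric(0), col = numeric(0),
                        gene = character(0), probability = numeric(0),
                        status = character(0), cell_id = integer(0))
  if (nrow(decoded) == 0) return(new("DecodedSpots", spots = emptyDf))
  masked <- matrix(-1, d[1], d[2])
  pix <- cbind(decoded$row, decoded$col)
  masked[pix] <- proj[pix]
  ## tie-tolerant maxima: a decoded pixel survives unless a strictly larger
  ## value sits within the window; equal-valued neighbors of the same gene
  ## are then deduplicated (plateaus), while ties of different genes remain
  ## distinct transcripts
  k <- max(1L, as.integer(minDistance))
  nm <- .neighborMax(masked, k)
  idx <- which(masked >= nm & masked > -0.5, arr.ind = TRUE)
  if (nrow(idx) == 0) return(new("DecodedSpots", spots = emptyDf))
  key <- paste(decoded$row, decoded$col)
  at0 <- match(paste(idx[, 1], idx[, 2]), key)
  ord <- order(-masked[idx], idx[, 1], idx[, 2])
  keep <- logical(0)
  kr <- kc <- numeric(0); kg <- character(0); kv <- numeric(0)
  for (i in ord) {
    r <- idx[i, 1]; c <- idx[i, 2]
    v <- masked[r, c]; g <- decoded$gene[at0[i]]
    dup <- any(abs(kr - r) <= k & abs(kc - c) <= k & kv == v & kg == g)
    if (!dup) {
      kr <- c(kr, r); kc <- c(kc, c); kg <- c(kg, g); kv <- c(kv, v)
    }
  }
  peaks <- data.frame(row = kr, col = kc)
  at <- match(paste(peaks$row, peaks$col), key)
  spots <- data.frame(row = peaks$row, col = peaks$col,
                      gene = decoded$gene[at],
                      probability = decoded$probability[at],
                      status = decoded$status[at],
                      cell_id = NA_integer_)
  new("DecodedSpots", spots = spots)
}

#' @describeIn extractDecodedSpots accessor: the transcript table.
#' @param x a [DecodedSpots-class].
#' @export
decodedSpots <- function(x) x@spots

setMethod("show", "DecodedSpots", function(object) {
  s <- object@spots
  cat(sprintf("DecodedSpots: %d transcripts, %d genes\n", nrow(s),
              length(unique(s$gene))))
  if (nrow(s) > 0) print(head(s, 5))
})

#' Assign transcripts to segmented cells
#'
#' Looks up each transcript's (rounded) pixel in an integer label mask
#' (0 = no cell) and tallies a cell-by-gene count table; transcripts on
#' label 0 are counted as extracellular (row `"0"`).
#'
#' @param spots a [DecodedSpots-class] or data.frame with `row`, `col`,
#'   `gene`.
#' @param labelMask integer matrix of cell labels.
#' @return list: `spots` (input with `cell_id` filled) and `counts`
#'   (sparse cells x genes [Matrix::sparseMatrix()]).
#' @export
assignToCells <- function(spots, labelMask) {
  df <- if (is(spots, "DecodedSpots")) spots@spots else spots
  if (nrow(df) == 0) {
    counts <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                   dims = c(0, 0))
    if (is(spots, "DecodedSpots")) spots@spots <- df
    return(list(spots = spots, counts = counts))
  }
  pr <- pmin(pmax(roundHalfAway(df$row), 1), nrow(labelMask))
  pc <- pmin(pmax(roundHalfAway(df$col), 1), ncol(labelMask))
  df$cell_id <- as.integer(labelMask[cbind(pr, pc)])
  cells <- sort(unique(df$cell_id))
  genes <- sort(unique(df$gene))
  counts <- Matrix::sparseMatrix(i = match(df$cell_id, cells),
                                 j = match(df$gene, genes),
                                 x = rep(1, nrow(df)),
                                 dims = c(length(cells), length(genes)),
                                 dimnames = list(as.character(cells), genes))
  if (is(spots, "DecodedSpots")) {
    spots@spots <- df
    list(spots = spots, counts = counts)
  } else list(spots = df, counts = counts)
}
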