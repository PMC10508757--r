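#' Simulate a spot image
#'
#' Renders isotropic 2-D Gaussian spots at uniformly random subpixel locations
#' on top of a background image. The spot count is uniform over
#' `nSpotsRange`; amplitudes and widths are drawn from truncated normal
#' distributions chosen to resemble diffraction-limited smFISH puncta at a
#' ~110 nm pixel scale. Optional additive Gaussian camera noise.
#'
#' @param shape integer vector `c(H, W)`.
#' @param nSpotsRange inclusive integer interval for the spot count.
#' @param amplitudeMean,amplitudeSd,amplitudeMin amplitude distribution
#'   (normal, truncated below at `amplitudeMin`), arbitrary intensity units.
#' @param sigmaMean,sigmaSd,sigmaMin spot width distribution, pixels.
#' @param background scalar or `H x W` matrix (e.g. an autofluorescence image).
#' @param noiseSd additive Gaussian noise sd (0 disables noise).
#' @param margin exclusion margin in multiples of each spot's sigma kept away
#'   from the borders (0 = spots anywhere inside the image).
#' @param minSeparation minimum pairwise distance between spots, pixels
#'   (0 = unconstrained; enforced by rejection sampling).
#' @param seed integer seed; identical arguments and seed reproduce the image
#'   bit for bit.
#' @return list of class `"SimulatedSpotImage"`: `pixels` (H x W matrix),
#'   `truth` (data.frame `row`, `col`, `amplitude`, `sigma`; 1-based pixel
#'   coordinates, pixel centers at integers), `background`, `seed`.
#' @examples
#' sim <- simulateSpotImage(c(64, 64), c(10, 10), seed = 1)
#' nrow(sim$truth)
#' @export
simulateSpotImage <- function(shape = c(128, 128), nSpotsRange = c(30, 80),
                              amplitudeMean = 1.0, amplitudeSd = 0.2, amplitudeMin = 0.1,
                              sigmaMean = 1.5, sigmaSd = 0.3, sigmaMin = 0.5,
                              background = 0.1, noiseSd = 0.01,
                              margin = 0, minSeparation = 0, seed = NULL) {
  .stopifnot2(length(shape) == 2 && all(shape >= 1), "shape must be two positive integers")
  .stopifnot2(amplitudeSd >= 0 && sigmaSd >= 0, "distribution sd must be >= 0")
  .stopifnot2(length(nSpotsRange) == 2 && nSpotsRange[1] >= 0 &&
              nSpotsRange[2] >= nSpotsRange[1], "invalid nSpotsRange")
  if (!is.null(seed)) set.seed(seed)
  H <- shape[1]; W <- shape[2]
  bg <- if (is.matrix(background)) {
    .stopifnot2(all(dim(background) == shape), "background shape mismatch")
    background
  } else matrix(background, H, W)

  n <- if (nSpotsRange[1] == nSpotsRange[2]) nSpotsRange[1] else
    sample(nSpotsRange[1]:nSpotsRange[2], 1)
  amps <- if (n > 0) .rnormTrunc(n, amplitudeMean, amplitudeSd, amplitudeMin) else numeric(0)
  sigs <- if (n > 0) .rnormTrunc(n, sigmaMean, sigmaSd, sigmaMin) else numeric(0)
  rows <- numeric(n); cols <- numeric(n)
  for (s in seq_len(n)) {
    m <- margin * sigs[s]
    for (try in seq_len(2000L)) {
      r0 <- runif(1, 1 + m, H - m); c0 <- runif(1, 1 + m, W - m)
      if (minSeparation <= 0 || s == 1 ||
          all((rows[seq_len(s - 1)] - r0)^2 + (cols[seq_len(s - 1)] - c0)^2 >=
              minSeparation^2)) break
      if (try == 2000L) stop("could not satisfy minSeparation", call. = FALSE)
    }
    rows[s] <- r0; cols[s] <- c0
  }
  img <- bg + .renderGaussians(shape, rows, cols, amps, sigs)
  if (noiseSd > 0) img <- img + matrix(rnorm(H * W, 0, noiseSd), H, W)
  structure(list(pixels = img,
                 truth = data.frame(row = rows, col = cols,
                                    amplitude = amps, sigma = sigs),
                 background = bg, seed = seed),
            class = "SimulatedSpotImage")
}

#' Simulate a detection information matrix
#'
#' Draws latent cluster labels `z ~ Bernoulli(priorTrue)` and, per annotator
#' `i`, detections `x[c, i] ~ Bernoulli(tpr[i])` when `z[c] = 1` and
#' `Bernoulli(fpr[i])` when `z[c] = 0`. Unlike matrices built from real
#' detections, simulated rows may be all zero, so that column means equal
#' `priorTrue * tpr + (1 - priorTrue) * fpr` exactly in expectation.
#'
#' @param nClusters number of clusters (rows).
#' @param tprs,fprs per-annotator detection probabilities, equal lengths,
#'   each in \[0, 1\].
#' @param priorTrue prior probability that a cluster is a true spot.
#' @param seed integer seed.
#' @return list of class `"SimulatedDetectionSet"`: `z` (0/1 vector), `x`
#'   (binary `nClusters x A` matrix), `tprs`, `fprs`, `priorTrue`.
#' @export
simulateDetectionMatrix <- function(nClusters, tprs, fprs, priorTrue = 0.5,
                                    seed = NULL) {
  .stopifnot2(nClusters >= 1, "nClusters must be >= 1")
  .stopifnot2(length(tprs) == length(fprs), "tprs and fprs lengths differ")
  .stopifnot2(all(c(tprs, fprs, priorTrue) >= 0 & c(tprs, fprs, priorTrue) <= 1),
              "probabilities must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  A <- length(tprs)
  z <- rbinom(nClusters, 1, priorTrue)
  p <- outer(z, tprs) + outer(1 - z, fprs)
  x <- matrix(rbinom(nClusters * A, 1, as.vector(p)), nClusters, A)
  colnames(x) <- names(tprs) %||% paste0("annotator", seq_len(A))
  structure(list(z = z, x = x, tprs = tprs, fprs = fprs, priorTrue = priorTrue),
            class = "SimulatedDetectionSet")
}

#' Simulate barcode intensity traces
#'
#' Draws per-spot traces over the `nRounds * nChannels` barcode bits: "on"
#' bits sample `onDist`, "off" bits sample `offDist`, and each on bit is
#' independently replaced by an `offDist` draw with probability
#' `dropoutRate` (bit dropout). Defaults are Beta(20, 2) / Beta(2, 20) —
#' strictly inside (0, 1), as a relaxed-Bernoulli likelihood requires, and
#' mimicking the spot-probability outputs of the detection model.
#'
#' @param codebook a [Codebook-class]; genes are sampled uniformly over the
#'   real (non-background) genes.
#' @param nSpots number of traces.
#' @param onDist,offDist functions `n -> n draws in (0, 1)`.
#' @param dropoutRate per-on-bit dropout probability in \[0, 1\].
#' @param seed integer seed.
#' @return list of class `"SimulatedBarcodeSet"`: `traces`
#'   (`nSpots x bits` matrix), `geneIds` (row indices into
#'   `barcodeMatrix(codebook)`), `dropped` (binary matrix of dropped on
#'   bits), `dropoutRate`.
#' @export
simulateBarcodeTraces <- function(codebook, nSpots,
                                  onDist = function(n) rbeta(n, 20, 2),
                                  offDist = function(n) rbeta(n, 2, 20),
                                  dropoutRate = 0, seed = NULL) {
  .stopifnot2(is(codebook, "Codebook"), "codebook must be a Codebook")
  .stopifnot2(dropoutRate >= 0 && dropoutRate <= 1, "dropoutRate must lie in [0, 1]")
  .stopifnot2(nSpots >= 1, "nSpots must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  B <- barcodeMatrix(codebook)
  nb <- ncol(B)
  geneIds <- sample.int(nrow(B), nSpots, replace = TRUE)
  bits <- B[geneIds, , drop = FALSE]
  dropped <- matrix(rbinom(nSpots * nb, 1, dropoutRate), nSpots, nb) * bits
  effective <- bits * (1 - dropped)
  traces <- matrix(offDist(nSpots * nb), nSpots, nb)
  onIdx <- which(effective == 1)
  traces[onIdx] <- onDist(length(onIdx))
  bad <- traces <= 0 | traces >= 1
  if (any(bad)) traces[bad] <- pmin(pmax(traces[bad], 1e-4), 1 - 1e-4)
  structure(list(traces = traces, geneIds = geneIds, dropped = dropped,
                 dropoutRate = dropoutRate),
            class = "SimulatedBarcodeSet")
}

#' Write simulated barcode traces to CSV
#'
#' One row per spot: the `nRounds * nChannels` trace columns (named
#' `r{round}c{channel}`) followed by `gene_id` (the codebook row index).
#'
#' @param set a `"SimulatedBarcodeSet"`.
#' @param codebook the [Codebook-class] the traces were simulated from
#'   (provides column names).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeTraceCSV <- function(set, codebook, path) {
  R <- nRounds(codebook); C <- nChannels(codebook)
  cn <- as.vector(t(outer(seq_len(R), seq_len(C),
                          function(r, c) sprintf("r%dc%d", r, c))))
  df <- as.data.frame(set$traces)
  names(df) <- cn
  df$gene_id <- set$geneIds
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a simulated image and its ground truth to disk
#'
#' The image goes to 32-bit float TIFF, the ground-truth spot table to CSV
#' (columns `row`, `col`, `amplitude`, `sigma`).
#'
#' @param sim a `"SimulatedSpotImage"`.
#' @param imagePath,truthPath output paths.
#' @return invisibly, the two paths.
#' @export
writeSimulatedImage <- function(sim, imagePath, truthPath) {
  writeImageTIFF(sim$pixels, imagePath)
  write.csv(sim$truth, truthPath, row.names = FALSE)
  invisible(c(imagePath, truthPath))
}
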