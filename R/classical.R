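#' Classical spot detection
#'
#' Pixel-resolution candidate detection with one of three classical
#' operators, used as noisy "annotators" for consensus labeling:
#' \describe{
#'   \item{`local_max`}{local maxima of the raw image above `threshold`.}
#'   \item{`dog`}{difference of Gaussians (`sigma` vs `sigma * 1.6`), local
#'     maxima of the response above `threshold`.}
#'   \item{`log`}{scale-normalized negative Laplacian of Gaussian, local
#'     maxima above `threshold`.}
#' }
#' The image is expected min-max normalized to \[0, 1\]
#' (see [preprocessImage()]). External detectors (e.g. centroid-finding or
#' Gaussian-mask algorithms run elsewhere) can join the consensus step
#' through the shared spot CSV format instead.
#'
#' @param image 2-D numeric matrix in \[0, 1\].
#' @param method one of `"local_max"`, `"dog"`, `"log"`.
#' @param threshold detection threshold on the operator response.
#' @param minDistance half-width (pixels) of the local-maximum window.
#' @param sigma blob scale for `dog`/`log`, pixels.
#' @param annotatorId label stored with the detections.
#' @return data.frame (a "spot list") with columns `row`, `col`, `score`,
#'   `annotator`.
#' @examples
#' img <- simulateSpotImage(c(64, 64), c(5, 5), noiseSd = 0, seed = 2)
#' d <- detectClassical(preprocessImage(img$pixels), "log", threshold = 0.1)
#' nrow(d)
#' @export
detectClassical <- function(image, method = c("local_max", "dog", "log"),
                            threshold = 0.2, minDistance = 2, sigma = 1.5,
                            annotatorId = NULL) {
  method <- match.arg(method)
  .stopifnot2(is.matrix(image) && all(is.finite(image)), "image must be a finite matrix")
  resp <- switch(method,
    local_max = image,
    dog = .gaussBlur(image, sigma) - .gaussBlur(image, sigma * 1.6),
    log = {
      sm <- .gaussBlur(image, sigma)
      H <- nrow(sm); W <- ncol(sm)
      pad <- sm[c(1, seq_len(H), H), c(1, seq_len(W), W)]
      lap <- pad[seq_len(H), 2:(W + 1)] + pad[3:(H + 2), 2:(W + 1)] +
             pad[2:(H + 1), seq_len(W)] + pad[2:(H + 1), 3:(W + 2)] -
             4 * sm
      -sigma^2 * lap
    })
  det <- .localMaxima(resp, threshold, minDistance)
  det <- det[!duplicated(det[, c("row", "col")]), , drop = FALSE]
  det$annotator <- rep(annotatorId %||% method, nrow(det))
  rownames(det) <- NULL
  det
}

#' Subpixel refinement by isotropic 2-D Gaussian fitting
#'
#' Crops a `window x window` (default 10 x 10) region around a pixel-level
#' candidate and fits `A * exp(-((r - r0)^2 + (c - c0)^2) / (2 s^2)) + b` by
#' bounded nonlinear least squares (Levenberg-Marquardt). Initial values:
#' mean at the candidate pixel, amplitude 1 (images are min-max normalized),
#' sigma 0.5 px; the fitted mean is constrained to the central 20% of the
#' crop and sigma to (0, 3\]. On fit failure or a degenerate (flat) crop the
#' candidate pixel is returned unchanged with `refined = FALSE`.
#'
#' The even window spans rows `[r - 5, r + 4]` and is clamped (shifted) at
#' image borders so it always holds `window^2` pixels.
#'
#' @param image 2-D numeric matrix, min-max normalized.
#' @param pixelSpot integer-valued `c(row, col)` candidate.
#' @param window crop side length, pixels.
#' @return numeric `c(row, col)` with attribute `refined` (logical) and
#'   `sigma` (fitted width, NA when unrefined).
#' @export
gaussianSubpixelRefine <- function(image, pixelSpot, window = 10) {
  H <- nrow(image); W <- ncol(image)
  .stopifnot2(window >= 4 && window <= min(H, W), "window must fit inside the image")
  r <- roundHalfAway(pixelSpot[1]); c <- roundHalfAway(pixelSpot[2])
  half <- floor(window / 2)
  r1 <- min(max(1, r - half), H - window + 1); c1 <- min(max(1, c - half), W - window + 1)
  crop <- image[r1:(r1 + window - 1), c1:(c1 + window - 1)]
  unref <- function() structure(c(pixelSpot[1], pixelSpot[2]),
                                refined = FALSE, sigma = NA_real_)
  if (sd(crop) < 1e-12) return(unref())

  rr <- as.vector(row(crop)); cc <- as.vector(col(crop)); vv <- as.vector(crop)
  ctr <- (1 + window) / 2                      # crop center (e.g. 5.5 for 10)
  band <- 0.1 * window                          # central 20% of the crop
  lower <- c(ctr - band, ctr - band, 0, 1e-3, -Inf)
  upper <- c(ctr + band, ctr + band, Inf, 3, Inf)
  start <- c(r - r1 + 1, c - c1 + 1, 1, 0.5, min(vv))
  # a border-clamped window can leave the candidate outside the central
  # band: the location constraint cannot hold, so stay unrefined
  if (any(start[1:2] < lower[1:2] | start[1:2] > upper[1:2])) return(unref())
  resid <- function(p) vv - (p[3] * exp(-((rr - p[1])^2 + (cc - p[2])^2) / (2 * p[4]^2)) + p[5])
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper, fn = resid,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 200, ftol = 1e-13, ptol = 1e-13)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance) || fit$par[3] <= 1e-6) return(unref())
  structure(c(fit$par[1] + r1 - 1, fit$par[2] + c1 - 1),
            refined = TRUE, sigma = fit$par[4])
}

#' Refine all spots in a spot list
#'
#' Applies [gaussianSubpixelRefine()] to every row of a pixel-level spot list.
#'
#' @param image 2-D numeric matrix, min-max normalized.
#' @param spots data.frame with `row`, `col` columns.
#' @param window crop side length.
#' @return the spot list with refined `row`, `col` and a logical `refined`
#'   column.
#' @export
refineSpots <- function(image, spots, window = 10) {
  if (nrow(spots) == 0) { spots$refined <- logical(0); return(spots) }
  out <- t(vapply(seq_len(nrow(spots)), function(i) {
    z <- gaussianSubpixelRefine(image, c(spots$row[i], spots$col[i]), window)
    c(z[1], z[2], as.numeric(attr(z, "refined")))
  }, numeric(3)))
  spots$row <- out[, 1]; spots$col <- out[, 2]; spots$refined <- out[, 3] > 0
  spots
}
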