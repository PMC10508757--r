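#' Codebook: gene barcodes over imaging rounds and channels
#'
#' Binary on/off patterns (one row per gene) over `nRounds * nChannels`
#' barcode bits, in round-major bit order (`r1c1, r1c2, ..., r2c1, ...`).
#' An all-zero "background" barcode is always appended as the last row: it
#' absorbs pixels with no signal in any round, i.e. false-positive detections.
#'
#' @slot geneNames character vector including the final `"background"` entry.
#' @slot barcodes binary matrix, `(genes + 1) x (nRounds * nChannels)`.
#' @slot nRounds integer, number of imaging rounds.
#' @slot nChannels integer, number of fluorescence channels per round.
#' @export
setClass("Codebook",
  representation(geneNames = "character", barcodes = "matrix",
                 nRounds = "integer", nChannels = "integer"),
  validity = function(object) {
    msg <- NULL
    b <- object@barcodes
    if (!all(b %in% c(0, 1))) msg <- c(msg, "barcodes must be binary")
    if (nrow(b) != length(object@geneNames))
      msg <- c(msg, "geneNames length must match barcode rows")
    if (ncol(b) != object@nRounds * object@nChannels)
      msg <- c(msg, "barcode width must equal nRounds * nChannels")
    if (anyDuplicated(apply(b, 1, paste, collapse = "")))
      msg <- c(msg, "barcode rows must be unique")
    if (any(b[nrow(b), ] != 0) || object@geneNames[length(object@geneNames)] != "background")
      msg <- c(msg, "last row must be the all-zero 'background' barcode")
    if (is.null(msg)) TRUE else msg
  }
)

#' Pixel-wise spot prediction
#'
#' Output of the spot detection model on one image: a pixel-wise spot
#' probability map and two regression maps holding the signed subpixel offset
#' (spot minus pixel, in pixels) to the nearest spot along rows and columns.
#'
#' @slot probability matrix in \[0, 1\], same shape as the input image.
#' @slot dy,dx numeric matrices of row/column offsets, pixels.
#' @export
setClass("SpotPrediction",
  representation(probability = "matrix", dy = "matrix", dx = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (any(object@probability < 0 | object@probability > 1))
      msg <- c(msg, "probability must lie in [0, 1]")
    if (!identical(dim(object@probability), dim(object@dy)) ||
        !identical(dim(object@probability), dim(object@dx)))
      msg <- c(msg, "probability/dy/dx shapes must match")
    if (is.null(msg)) TRUE else msg
  }
)

#' EM consensus fit over a detection information matrix
#'
#' Result of fitting the two-state Bernoulli annotator model: per-annotator
#' true/false positive rates, the per-cluster posterior probability of being a
#' true spot, and the observed-data log-likelihood trace over EM iterations.
#'
#' @slot tpr,fpr named numeric vectors, one entry per annotator, in (0, 1).
#' @slot posterior numeric vector, per-cluster `p(z = 1 | x, theta)`.
#' @slot prior scalar prior probability of a true spot.
#' @slot logLik numeric vector, observed-data log-likelihood after each
#'   iteration (element 1 is at the initial parameters).
#' @export
setClass("ConsensusFit",
  representation(tpr = "numeric", fpr = "numeric", posterior = "numeric",
                 prior = "numeric", logLik = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@tpr) != length(object@fpr))
      msg <- c(msg, "tpr/fpr lengths differ")
    if (any(c(object@tpr, object@fpr, object@posterior) < 0) ||
        any(c(object@tpr, object@fpr, object@posterior) > 1))
      msg <- c(msg, "rates and posteriors must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' Fully convolutional spot detection model
#'
#' A pixel-classification plus subpixel-regression network: a stack of 3x3
#' convolution + batch-norm + ReLU blocks whose depth fixes the receptive
#' field, followed by a 1x1 classification head (spot probability logit) and
#' a 1x1 regression head (row/column subpixel offsets).
#'
#' @slot config list: `receptiveField`, `nFilters`, `depth`.
#' @slot params list of layer parameter lists (weights, biases, batch-norm
#'   scale/shift and running statistics).
#' @slot history data.frame of per-epoch training/validation losses.
#' @slot trained logical.
#' @export
setClass("SpotNet",
  representation(config = "list", params = "list", history = "data.frame",
                 trained = "logical"))

#' Decoded transcripts
#'
#' Coordinates with gene identity, assignment probability, assignment status
#' (`assigned`, `background`, `unknown`, `rescued_error`, `rescued_mixed`)
#' and optional cell label.
#'
#' @slot spots data.frame with columns `row`, `col`, `gene`, `probability`,
#'   `status`, `cell_id`.
#' @export
setClass("DecodedSpots",
  representation(spots = "data.frame"),
  validity = function(object) {
    need <- c("row", "col", "gene", "probability", "status", "cell_id")
    msg <- NULL
    if (!all(need %in% names(object@spots)))
      msg <- c(msg, paste("spots must have columns:", paste(need, collapse = ", ")))
    else {
      p <- object@spots$probability
      if (any(!is.na(p) & (p < 0 | p > 1))) msg <- c(msg, "probability outside [0, 1]")
      ok <- c("assigned", "background", "unknown", "rescued_error", "rescued_mixed")
      if (!all(object@spots$status %in% ok)) msg <- c(msg, "invalid status value")
    }
    if (is.null(msg)) TRUE else msg
  }
)
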