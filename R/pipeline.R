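#' Run the singleplex detection pipeline on one image
#'
#' Preprocess, predict pixel-wise spot probability, postprocess into a
#' subpixel spot list, then optionally mask bright background regions and
#' assign spots to segmented cells. When `outputDir` is given, the spot CSV
#' and a reproducibility manifest are written.
#'
#' @param image 2-D numeric matrix, or a TIFF path.
#' @param model a trained [SpotNet-class], or any function
#'   `image -> SpotPrediction` (e.g. a stub in tests).
#' @param threshold,minDistance postprocessing parameters
#'   (see [postprocessPrediction()]).
#' @param backgroundImage optional background image or logical mask for
#'   [applyBackgroundMask()].
#' @param maskThreshold background mask threshold.
#' @param labelMask optional integer cell label mask.
#' @param outputDir optional output directory.
#' @param seed recorded in the manifest (the path is deterministic).
#' @return list: `spots` (data.frame), `prediction` (a
#'   [SpotPrediction-class]), `counts` (cells x genes, when `labelMask`
#'   given).
#' @export
runSingleplex <- function(image, model, threshold = 0.95, minDistance = 1,
                          backgroundImage = NULL, maskThreshold = 0.5,
                          labelMask = NULL, outputDir = NULL, seed = NULL) {
  if (is.character(image)) image <- readImageTIFF(image)
  img <- preprocessImage(image)
  pred <- if (is.function(model)) model(img) else predictSpotNet(model, img)
  .stopifnot2(is(pred, "SpotPrediction"), "model must produce a SpotPrediction")
  spots <- postprocessPrediction(pred, threshold, minDistance)
  if (!is.null(backgroundImage))
    spots <- applyBackgroundMask(spots, backgroundImage, maskThreshold)
  counts <- NULL
  if (!is.null(labelMask) && nrow(spots) > 0) {
    ac <- assignToCells(spots, labelMask)
    spots <- ac$spots; counts <- ac$counts
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    writeSpotCSV(spots, file.path(outputDir, "spots.csv"),
                 annotatorId = "spotnet")
    .writeManifest(outputDir, list(threshold = threshold,
                                   minDistance = minDistance,
                                   maskThreshold = maskThreshold), seed)
  }
  list(spots = spots, prediction = pred, counts = counts)
}

#' Run the multiplex decoding pipeline
#'
#' Per-round/channel spot-probability prediction, decodable-pixel selection,
#' barcode mixture fitting, gene assignment, error and mixed rescues,
#' optional background masking, decoded-spot extraction and optional
#' per-cell aggregation.
#'
#' @param images list of `nRounds * nChannels` matrices (or TIFF paths) in
#'   round-major order, or a prediction-probability array `H x W x bits`
#'   when detection was run elsewhere.
#' @param codebook a [Codebook-class].
#' @param model a trained [SpotNet-class] or function
#'   `image -> SpotPrediction`; ignored when `images` is already a
#'   probability array.
#' @param selectThreshold max-projection pixel selection threshold.
#' @param probThreshold gene assignment threshold.
#' @param family mixture family, see [fitBarcodeMixture()].
#' @param sviSteps,sviLr,minibatch optimizer schedule.
#' @param rescue apply [errorRescue()] and [mixedRescue()].
#' @param backgroundImage,maskThreshold optional background masking.
#' @param labelMask optional integer cell label mask.
#' @param minDistance spacing for decoded-spot extraction.
#' @param outputDir optional output directory (transcripts CSV, cell-gene
#'   matrix, manifest).
#' @param seed seed for the mixture fit.
#' @return list: `spots` (a [DecodedSpots-class]), `assignments` (per-pixel
#'   data.frame), `mixture` (fitted `"BarcodeMixture"`), `counts` (when
#'   `labelMask` given).
#' @export
runMultiplex <- function(images, codebook, model = NULL,
                         selectThreshold = 0.01, probThreshold = 0.95,
                         family = "relaxed_bernoulli", sviSteps = 1000,
                         sviLr = 0.01, minibatch = 1024, rescue = TRUE,
                         backgroundImage = NULL, maskThreshold = 0.5,
                         labelMask = NULL, minDistance = 1,
                         outputDir = NULL, seed = 1) {
  nb <- nRounds(codebook) * nChannels(codebook)
  if (is.array(images) && length(dim(images)) == 3) {
    .stopifnot2(dim(images)[3] == nb,
                "probability stack depth must equal codebook bits")
    stack <- images
  } else {
    .stopifnot2(is.list(images), "images must be a list or a 3-D array")
    if (length(images) != nb)
      stop(sprintf("expected %d images (rounds x channels), got %d",
                   nb, length(images)), call. = FALSE)
    preds <- lapply(images, function(im) {
      if (is.character(im)) im <- readImageTIFF(im)
      img <- preprocessImage(im)
      p <- if (is.function(model)) model(img) else predictSpotNet(model, img)
      p@probability
    })
    d <- dim(preds[[1]])
    stack <- array(unlist(preds), c(d[1], d[2], nb))
  }
  px <- selectDecodablePixels(stack, selectThreshold)
  if (!is.null(backgroundImage))
    px <- applyBackgroundMask(px, backgroundImage, maskThreshold)
  if (nrow(px$coords) == 0) {
    empty <- new("DecodedSpots", spots = data.frame(
      row = numeric(0), col = numeric(0), gene = character(0),
      probability = numeric(0), status = character(0), cell_id = integer(0)))
    return(list(spots = empty, assignments = NULL, mixture = NULL, counts = NULL))
  }
  mix <- fitBarcodeMixture(px, codebook, family = family, steps = sviSteps,
                           lr = sviLr, minibatch = minibatch, seed = seed)
  asg <- assignBarcodes(px, mix, codebook, probThreshold)
  if (rescue) {
    asg <- errorRescue(asg, px, codebook)
    asg <- mixedRescue(asg, px$traces[seq_len(nrow(px$traces)), , drop = FALSE],
                       codebook, probThreshold)
  }
  spots <- extractDecodedSpots(asg, stack, minDistance)
  counts <- NULL
  if (!is.null(labelMask) && nrow(decodedSpots(spots)) > 0) {
    ac <- assignToCells(spots, labelMask)
    spots <- ac$spots; counts <- ac$counts
  }
  if (!is.null(outputDir)) {
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(decodedSpots(spots), file.path(outputDir, "transcripts.csv"),
              row.names = FALSE)
    if (!is.null(counts)) writeCellGeneMatrix(counts, file.path(outputDir, "cell_gene"))
    .writeManifest(outputDir, list(selectThreshold = selectThreshold,
                                   probThreshold = probThreshold,
                                   family = family, rescue = rescue), seed)
  }
  list(spots = spots, assignments = asg, mixture = mix, counts = counts)
}

#' Consensus labeling of multi-annotator spot CSVs
#'
#' Convenience driver: clusters the detections of several annotators, builds
#' the detection information matrix, fits the EM consensus model and
#' extracts consensus spots. Matrices from several images are pooled into
#' one EM fit (one annotator parameter set spans the dataset).
#'
#' @param annotations data.frame with `row`, `col`, `annotator` and
#'   optionally `image_id` columns (pooled across images).
#' @param linkRadius clustering radius, pixels.
#' @param threshold consensus retention threshold.
#' @param ... passed to [fitEM()].
#' @return list: `spots` (per image when `image_id` present), `fit`
#'   (a [ConsensusFit-class]), `clusters`.
#' @export
runConsensus <- function(annotations, linkRadius = 1.5, threshold = 0.9, ...) {
  ids <- unique(annotations$image_id %||% "image1")
  annotations$image_id <- annotations$image_id %||% "image1"
  perImage <- lapply(ids, function(id)
    clusterDetections(annotations[annotations$image_id == id, ], linkRadius))
  annot <- sort(unique(annotations$annotator))
  mats <- lapply(perImage, buildDetectionMatrix, annotatorIds = annot)
  x <- do.call(rbind, mats)
  fit <- fitEM(x, ...)
  offsets <- cumsum(c(0, vapply(mats, nrow, 1L)))
  spots <- do.call(rbind, lapply(seq_along(ids), function(k) {
    p <- fit@posterior[(offsets[k] + 1):offsets[k + 1]]
    s <- extractConsensus(perImage[[k]], p, threshold)
    if (nrow(s) > 0) s$image_id <- ids[k]
    s
  }))
  list(spots = spots, fit = fit, clusters = perImage)
}
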