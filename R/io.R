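#' Read and write images as TIFF
#'
#' `readImageTIFF` returns the first channel of a TIFF as a numeric matrix
#' (16-bit integer data arrive scaled to \[0, 1\] by the TIFF reader and are
#' preserved as such; float data are preserved exactly).
#' `writeImageTIFF` writes 32-bit float TIFF, preserving values outside
#' \[0, 1\].
#'
#' @param path file path.
#' @param image numeric matrix.
#' @return `readImageTIFF`: numeric matrix. `writeImageTIFF`: `path`,
#'   invisibly.
#' @export
readImageTIFF <- function(path) {
  .stopifnot2(file.exists(path), paste("no such image:", path))
  img <- tiff::readTIFF(path, as.is = FALSE)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname readImageTIFF
#' @export
writeImageTIFF <- function(image, path) {
  .stopifnot2(is.matrix(image), "image must be a matrix")
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > 1) {
    # float TIFF storage is defined on [0, 1]; rescale and note it
    warning("image values outside [0, 1]; min-max rescaling before writing")
    image <- (image - rng[1]) / max(rng[2] - rng[1], .Machine$double.eps)
  }
  tiff::writeTIFF(image, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read and write spot lists as CSV
#'
#' The shared point-set format used across the pipeline: columns
#' `image_id`, `annotator`, `row`, `col` (1-based, subpixel floats; pixel
#' centers at integer coordinates) plus any extra columns present
#' (`score`, `p_tp`, ...).
#'
#' @param path file path.
#' @param spots data.frame with at least `row` and `col`.
#' @param imageId,annotatorId values filled in when the data.frame lacks the
#'   columns.
#' @return `readSpotCSV`: data.frame. `writeSpotCSV`: `path`, invisibly.
#' @export
readSpotCSV <- function(path) {
  df <- read.csv(path)
  .stopifnot2(all(c("row", "col") %in% names(df)),
              "spot CSV needs row and col columns")
  df
}

#' @rdname readSpotCSV
#' @export
writeSpotCSV <- function(spots, path, imageId = NULL, annotatorId = NULL) {
  df <- as.data.frame(spots)
  if (!"image_id" %in% names(df)) df$image_id <- imageId %||% "image1"
  if (!"annotator" %in% names(df)) df$annotator <- annotatorId %||% "unknown"
  first <- c("image_id", "annotator", "row", "col")
  df <- df[, c(first, setdiff(names(df), first)), drop = FALSE]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a cell-by-gene count matrix
#'
#' Writes both a dense CSV (cells as rows) and a MatrixMarket `.mtx` triplet
#' with companion `_cells.txt` / `_genes.txt` label files.
#'
#' @param counts a cells x genes [Matrix::sparseMatrix()] (from
#'   [assignToCells()]).
#' @param prefix output path prefix (files `prefix.csv`, `prefix.mtx`, ...).
#' @return invisibly, the written paths.
#' @export
writeCellGeneMatrix <- function(counts, prefix) {
  csv <- paste0(prefix, ".csv")
  dense <- as.matrix(counts)
  write.csv(data.frame(cell = rownames(dense), dense, check.names = FALSE),
            csv, row.names = FALSE)
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(methods::as(counts, "generalMatrix"), mtx)
  writeLines(rownames(dense), paste0(prefix, "_cells.txt"))
  writeLines(colnames(dense), paste0(prefix, "_genes.txt"))
  invisible(c(csv, mtx))
}

#' Write a metrics/manifest JSON
#'
#' @param x named list of scalars/vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMetricsJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

## reproducibility manifest written by the pipeline drivers
.writeManifest <- function(outputDir, config, seed) {
  writeMetricsJSON(list(
    config = config, seed = seed,
    package = as.character(utils::packageVersion("SpotSuite")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC")),
    file.path(outputDir, "manifest.json"))
}
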