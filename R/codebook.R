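#' Construct a Codebook
#'
#' Builds a [Codebook-class] from per-gene binary barcodes. The all-zero
#' `"background"` barcode is appended automatically (it must not be supplied).
#'
#' @param geneNames character vector of gene names.
#' @param barcodes binary matrix, genes x (nRounds * nChannels), round-major
#'   bit order.
#' @param nRounds,nChannels integers describing the imaging layout.
#' @return A [Codebook-class] object.
#' @examples
#' cb <- Codebook(c("g1", "g2"), rbind(c(1, 1, 0, 0), c(0, 0, 1, 1)), 2, 2)
#' cb
#' @export
Codebook <- function(geneNames, barcodes, nRounds, nChannels) {
  barcodes <- as.matrix(barcodes)
  storage.mode(barcodes) <- "double"
  .stopifnot2(all(barcodes %in% c(0, 1)), "barcodes must be binary (0/1)")
  .stopifnot2(length(geneNames) == nrow(barcodes),
              "geneNames length must equal barcode rows")
  .stopifnot2(!"background" %in% geneNames,
              "'background' is reserved; it is appended automatically")
  .stopifnot2(all(rowSums(barcodes) > 0), "gene barcodes must have >= 1 on bit")
  full <- rbind(barcodes, 0)
  rownames(full) <- c(geneNames, "background")
  new("Codebook", geneNames = c(geneNames, "background"), barcodes = full,
      nRounds = as.integer(nRounds), nChannels = as.integer(nChannels))
}

#' @describeIn Codebook gene names (excluding the background entry by default).
#' @param x,object a `Codebook`.
#' @param withBackground include the background row/name.
#' @export
geneNames <- function(x, withBackground = FALSE) {
  n <- x@geneNames
  if (withBackground) n else n[-length(n)]
}

#' @describeIn Codebook barcode matrix; background row included on request.
#' @export
barcodeMatrix <- function(x, withBackground = FALSE) {
  b <- x@barcodes
  if (withBackground) b else b[-nrow(b), , drop = FALSE]
}

#' @describeIn Codebook number of imaging rounds.
#' @export
nRounds <- function(x) x@nRounds

#' @describeIn Codebook number of channels per round.
#' @export
nChannels <- function(x) x@nChannels

setMethod("show", "Codebook", function(object) {
  cat(sprintf("Codebook: %d genes (+ background), %d rounds x %d channels = %d bits\n",
              length(object@geneNames) - 1L, object@nRounds, object@nChannels,
              ncol(object@barcodes)))
  cat(sprintf("  on-bits per gene: %s\n",
              paste(unique(rowSums(object@barcodes[-nrow(object@barcodes), , drop = FALSE])),
                    collapse = ", ")))
})

#' Generate a random constant-weight codebook
#'
#' Samples barcodes with a fixed number of on bits and a minimum pairwise
#' Hamming distance, in the style of MERFISH-type error-robust codes
#' (e.g. 16 bits, 4 on bits, minimum distance 4).
#'
#' @param nGenes number of genes.
#' @param nRounds,nChannels imaging layout; barcode length is the product.
#' @param nOn on bits per barcode.
#' @param minHamming minimum pairwise Hamming distance between barcodes.
#' @param seed integer RNG seed.
#' @return A [Codebook-class].
#' @export
randomCodebook <- function(nGenes = 40, nRounds = 4, nChannels = 4, nOn = 4,
                           minHamming = 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- nRounds * nChannels
  .stopifnot2(nOn <= nb, "nOn exceeds barcode length")
  codes <- matrix(0, 0, nb)
  tries <- 0L
  while (nrow(codes) < nGenes) {
    cand <- numeric(nb); cand[sample.int(nb, nOn)] <- 1
    ok <- nrow(codes) == 0 ||
      all(rowSums(abs(sweep(codes, 2, cand, "-"))) >= minHamming)
    if (ok) codes <- rbind(codes, cand)
    tries <- tries + 1L
    if (tries > 200000L) stop("could not satisfy the distance constraint; relax minHamming")
  }
  Codebook(sprintf("gene%03d", seq_len(nGenes)), codes, nRounds, nChannels)
}

#' Read / write codebooks
#'
#' CSV layout: first column `gene`, remaining columns named `r{round}c{channel}`
#' holding 0/1. JSON layout: object with `n_rounds`, `n_channels` and a
#' `genes` map from name to bit vector. The background barcode is implicit
#' and never stored.
#'
#' @param path file path; format chosen by extension (`.csv` or `.json`).
#' @return `readCodebook` returns a [Codebook-class]; `writeCodebook` returns
#'   `path` invisibly.
#' @export
readCodebook <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    genes <- j$genes
    b <- do.call(rbind, genes)
    return(Codebook(names(genes), b, j$n_rounds, j$n_channels))
  }
  df <- read.csv(path, check.names = FALSE)
  .stopifnot2(names(df)[1] == "gene", "codebook CSV must start with a 'gene' column")
  bits <- as.matrix(df[, -1, drop = FALSE])
  if (!all(bits %in% c(0, 1))) stop("codebook CSV contains non-binary entries", call. = FALSE)
  cn <- colnames(bits)
  m <- regmatches(cn, regexec("^r([0-9]+)c([0-9]+)$", cn))
  .stopifnot2(all(lengths(m) == 3), "bit columns must be named r{round}c{channel}")
  R <- max(vapply(m, function(z) as.integer(z[2]), 1L))
  C <- max(vapply(m, function(z) as.integer(z[3]), 1L))
  .stopifnot2(ncol(bits) == R * C, "bit columns do not tile rounds x channels")
  ord <- order(vapply(m, function(z) as.integer(z[2]), 1L) * 1000 +
               vapply(m, function(z) as.integer(z[3]), 1L))
  Codebook(df$gene, bits[, ord, drop = FALSE], R, C)
}

#' @rdname readCodebook
#' @param codebook a [Codebook-class].
#' @export
writeCodebook <- function(codebook, path) {
  b <- barcodeMatrix(codebook)
  R <- nRounds(codebook); C <- nChannels(codebook)
  cn <- as.vector(t(outer(seq_len(R), seq_len(C), function(r, c) sprintf("r%dc%d", r, c))))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    genes <- lapply(seq_len(nrow(b)), function(i) as.integer(b[i, ]))
    names(genes) <- geneNames(codebook)
    jsonlite::write_json(list(n_rounds = R, n_channels = C, genes = genes),
                         path, auto_unbox = TRUE)
  } else {
    df <- data.frame(gene = geneNames(codebook), b, check.names = FALSE)
    names(df) <- c("gene", cn)
    write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
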