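#' Mutual-nearest-neighbor matching of two point sets
#'
#' A predicted spot is matched to a ground-truth spot iff the two are each
#' other's nearest neighbor (Euclidean, pixels) and their distance is at most
#' `threshold`. Every unmatched prediction is a false detection; every
#' unmatched truth is a miss. Nearest-neighbor ties are broken by lowest
#' index, so the pairing is deterministic.
#'
#' @param pred,truth data.frames with `row`, `col` columns (or 2-column
#'   matrices).
#' @param threshold maximum pairing distance, pixels.
#' @return list of class `"SpotMatching"`: `pairs` (data.frame `pred`,
#'   `truth`, `dist`), `unmatchedPred`, `unmatchedTruth` (index vectors),
#'   `threshold`.
#' @examples
#' p <- data.frame(row = c(1, 5), col = c(1, 5))
#' t <- data.frame(row = c(1.2, 9), col = c(1, 9))
#' matchMutualNearest(p, t, threshold = 1.5)$pairs
#' @export
matchMutualNearest <- function(pred, truth, threshold = 1.5) {
  .stopifnot2(threshold > 0, "threshold must be > 0")
  P <- as.matrix(as.data.frame(pred)[, c("row", "col")])
  T <- as.matrix(as.data.frame(truth)[, c("row", "col")])
  np <- nrow(P); nt <- nrow(T)
  empty <- data.frame(pred = integer(0), truth = integer(0), dist = numeric(0))
  if (np == 0 || nt == 0) {
    return(structure(list(pairs = empty, unmatchedPred = seq_len(np),
                          unmatchedTruth = seq_len(nt), threshold = threshold),
                     class = "SpotMatching"))
  }
  d <- sqrt(outer(P[, 1], T[, 1], "-")^2 + outer(P[, 2], T[, 2], "-")^2)
  nnOfPred <- apply(d, 1, which.min)           # ties -> lowest index
  nnOfTruth <- apply(d, 2, which.min)
  predIdx <- seq_len(np)
  mutual <- nnOfTruth[nnOfPred[predIdx]] == predIdx &
    d[cbind(predIdx, nnOfPred)] <= threshold
  pairs <- data.frame(pred = predIdx[mutual], truth = nnOfPred[mutual],
                      dist = d[cbind(predIdx, nnOfPred)][mutual])
  structure(list(pairs = pairs,
                 unmatchedPred = setdiff(predIdx, pairs$pred),
                 unmatchedTruth = setdiff(seq_len(nt), pairs$truth),
                 threshold = threshold),
            class = "SpotMatching")
}

#' Precision, recall and F1 from a matching
#'
#' `precision = pairs / nPred`, `recall = pairs / nTruth`, `F1` their
#' harmonic mean. Zero denominators yield 0 and set the `degenerate` flag.
#'
#' @param matching a `"SpotMatching"`.
#' @param nPred,nTruth set sizes; default recovered from the matching.
#' @return list `precision`, `recall`, `f1`, `nPairs`, `degenerate`.
#' @export
detectionMetrics <- function(matching,
                             nPred = nrow(matching$pairs) + length(matching$unmatchedPred),
                             nTruth = nrow(matching$pairs) + length(matching$unmatchedTruth)) {
  k <- nrow(matching$pairs)
  .stopifnot2(nPred >= k && nTruth >= k, "counts inconsistent with matching")
  degenerate <- nPred == 0 || nTruth == 0
  precision <- if (nPred > 0) k / nPred else 0
  recall <- if (nTruth > 0) k / nTruth else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(precision = precision, recall = recall, f1 = f1, nPairs = k,
       degenerate = degenerate)
}
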