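#' Cluster multi-annotator detections by proximity
#'
#' Builds a graph with one node per detection and an edge between every pair
#' within `linkRadius` (Euclidean, pixels); connected components are
#' detection clusters. Clusters are then screened so each holds at most one
#' detection per annotator: when an annotator contributes several members,
#' the one closest to the cluster centroid is retained (ties broken by input
#' order) and each surplus member is split off as its own singleton cluster.
#' Centroids are recomputed from retained members.
#'
#' @param annotations a data.frame with columns `row`, `col`, `annotator`
#'   (the row-bound spot lists of all annotators), or a list of such
#'   data.frames.
#' @param linkRadius maximum link distance, pixels.
#' @return list of class `"DetectionClusters"`: `members` (data.frame
#'   `row`, `col`, `annotator`, `cluster`), `centroids` (data.frame
#'   `row`, `col`, one per cluster), `annotators` (sorted ids).
#' @examples
#' a <- data.frame(row = c(10, 30), col = c(10, 30), annotator = "a")
#' b <- data.frame(row = c(10.5, 31.2), col = c(10.5, 29.9), annotator = "b")
#' clusterDetections(list(a, b))$centroids
#' @export
clusterDetections <- function(annotations, linkRadius = 1.5) {
  .stopifnot2(linkRadius > 0, "linkRadius must be > 0")
  if (is.data.frame(annotations)) ann <- annotations
  else ann <- do.call(rbind, lapply(annotations, function(d)
    d[, c("row", "col", "annotator")]))
  .stopifnot2(all(c("row", "col", "annotator") %in% names(ann)),
              "annotations need row/col/annotator columns")
  .stopifnot2(length(unique(ann$annotator)) >= 2, "need >= 2 annotators")
  .stopifnot2(all(is.finite(ann$row)) && all(is.finite(ann$col)),
              "coordinates must be finite")
  n <- nrow(ann)
  d <- as.matrix(stats::dist(cbind(ann$row, ann$col)))
  adj <- d <= linkRadius
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
  comp <- igraph::components(g)$membership

  ## screening: at most one member per annotator per cluster
  cluster <- comp
  nextId <- max(comp)
  for (cl in seq_len(max(comp))) {
    idx <- which(comp == cl)
    if (length(idx) < 2) next
    cen <- c(mean(ann$row[idx]), mean(ann$col[idx]))
    for (a in unique(ann$annotator[idx])) {
      ai <- idx[ann$annotator[idx] == a]
      if (length(ai) < 2) next
      dd <- (ann$row[ai] - cen[1])^2 + (ann$col[ai] - cen[2])^2
      keep <- ai[which.min(dd)]           # which.min: first minimum on ties
      for (s in setdiff(ai, keep)) {
        nextId <- nextId + 1L
        cluster[s] <- nextId
      }
    }
  }
  ids <- sort(unique(cluster))
  cluster <- match(cluster, ids)
  cen <- t(vapply(seq_len(max(cluster)), function(cl) {
    idx <- which(cluster == cl)
    c(mean(ann$row[idx]), mean(ann$col[idx]))
  }, numeric(2)))
  structure(list(
    members = data.frame(row = ann$row, col = ann$col,
                         annotator = ann$annotator, cluster = cluster),
    centroids = data.frame(row = cen[, 1], col = cen[, 2]),
    annotators = sort(unique(ann$annotator))),
    class = "DetectionClusters")
}

#' Build the detection information matrix
#'
#' Binary `C x A` matrix over clusters and annotators: entry `x[c, i] = 1`
#' iff annotator `i` contributed a detection to cluster `c`. Every row has at
#' least one 1, since a cluster only exists because some annotator detected
#' it.
#'
#' @param clusters a `"DetectionClusters"` object (already screened).
#' @param annotatorIds ordered annotator ids defining the columns.
#' @return binary matrix with annotator column names.
#' @export
buildDetectionMatrix <- function(clusters, annotatorIds = clusters$annotators) {
  m <- clusters$members
  .stopifnot2(all(m$annotator %in% annotatorIds), "unknown annotator id")
  if (anyDuplicated(m[, c("cluster", "annotator")]))
    stop("cluster holds duplicate detections from one annotator; screen first",
         call. = FALSE)
  C <- max(m$cluster); A <- length(annotatorIds)
  x <- matrix(0, C, A, dimnames = list(NULL, annotatorIds))
  x[cbind(m$cluster, match(m$annotator, annotatorIds))] <- 1
  x
}

.emLogLikParts <- function(x, tpr, fpr) {
  ## per-cluster log-likelihood under z=1 and z=0 (log space for stability)
  l1 <- as.vector(x %*% log(tpr) + (1 - x) %*% log1p(-tpr))
  l0 <- as.vector(x %*% log(fpr) + (1 - x) %*% log1p(-fpr))
  cbind(l1, l0)
}

#' EM expectation step
#'
#' Per-cluster posterior probability of being a true spot under the
#' conditionally independent Bernoulli annotator model:
#' `p(z=1 | x, theta) = L1 * prior / (L1 * prior + L0 * (1 - prior))` with
#' `Lz = prod_i theta_iz^x (1 - theta_iz)^(1-x)`. With the least-informative
#' prior 1/2 the prior cancels.
#'
#' @param x binary detection matrix, clusters x annotators.
#' @param tpr,fpr per-annotator rates in (0, 1).
#' @param prior prior probability of a true spot.
#' @return numeric vector of posteriors, one per cluster.
#' @export
eStep <- function(x, tpr, fpr, prior = 0.5) {
  .stopifnot2(all(c(tpr, fpr) > 0 & c(tpr, fpr) < 1),
              "tpr/fpr must lie strictly inside (0, 1)")
  ll <- .emLogLikParts(x, tpr, fpr)
  unname(1 / (1 + exp(log1p(-prior) - log(prior) + ll[, 2] - ll[, 1])))
}

#' EM maximization step
#'
#' Accumulates expected confusion counts per annotator — when `x[c,i] = 1`,
#' expected true positives `p_c` and false positives `1 - p_c`; when
#' `x[c,i] = 0`, expected false negatives `p_c` and true negatives
#' `1 - p_c` — and returns the maximum-likelihood updates
#' `TPR = ETP / (ETP + EFN)`, `FPR = EFP / (EFP + ETN)`. Degenerate
#' denominators fall back to 0.5 with a warning; all rates are clamped to
#' `[1e-4, 1 - 1e-4]` so subsequent likelihoods stay finite.
#'
#' @param x binary detection matrix.
#' @param posterior per-cluster posterior probabilities.
#' @return list with numeric vectors `tpr`, `fpr`.
#' @export
mStep <- function(x, posterior) {
  .stopifnot2(length(posterior) == nrow(x), "posterior length must match clusters")
  etp <- as.vector(crossprod(x, posterior))
  efp <- as.vector(crossprod(x, 1 - posterior))
  efn <- sum(posterior) - etp
  etn <- sum(1 - posterior) - efp
  tpr <- etp / (etp + efn)
  fpr <- efp / (efp + etn)
  if (any(!is.finite(tpr)) || any(!is.finite(fpr))) {
    warning("degenerate expected counts; affected rates set to 0.5")
    tpr[!is.finite(tpr)] <- 0.5
    fpr[!is.finite(fpr)] <- 0.5
  }
  eps <- 1e-4
  list(tpr = setNames(pmin(pmax(tpr, eps), 1 - eps), colnames(x)),
       fpr = setNames(pmin(pmax(fpr, eps), 1 - eps), colnames(x)))
}

#' Observed-data log-likelihood of the consensus model
#'
#' `sum_c log( prior * L1_c + (1 - prior) * L0_c )`, computed in log space.
#'
#' @inheritParams eStep
#' @return scalar log-likelihood.
#' @export
consensusLogLik <- function(x, tpr, fpr, prior = 0.5) {
  ll <- .emLogLikParts(x, tpr, fpr)
  sum(.rowLogSumExp(cbind(ll[, 1] + log(prior), ll[, 2] + log1p(-prior))))
}

#' Fit the consensus model by expectation maximization
#'
#' Alternates [eStep()] and [mStep()] for `nIter` iterations from initial
#' rate guesses (defaults 0.9 / 0.1, prior 1/2, 20 iterations — sufficient
#' for convergence to a local maximum on detection matrices of this kind).
#' The observed-data log-likelihood is recorded after each iteration and is
#' non-decreasing (EM guarantee).
#'
#' @param x binary detection matrix, clusters x annotators.
#' @param initTpr,initFpr initial per-annotator rates (scalars recycled).
#' @param prior prior probability of a true spot.
#' @param nIter number of EM iterations.
#' @return a [ConsensusFit-class].
#' @examples
#' sim <- simulateDetectionMatrix(2000, rep(0.9, 4), rep(0.1, 4), seed = 1)
#' fit <- fitEM(sim$x)
#' round(tpr(fit), 2)
#' @export
fitEM <- function(x, initTpr = 0.9, initFpr = 0.1, prior = 0.5, nIter = 20) {
  .stopifnot2(nrow(x) >= 1 && ncol(x) >= 1, "x must be non-empty")
  .stopifnot2(nIter >= 1, "nIter must be >= 1")
  A <- ncol(x)
  tpr <- rep_len(initTpr, A); fpr <- rep_len(initFpr, A)
  ll <- numeric(nIter + 1)
  ll[1] <- consensusLogLik(x, tpr, fpr, prior)
  post <- NULL
  for (it in seq_len(nIter)) {
    post <- eStep(x, tpr, fpr, prior)
    upd <- mStep(x, post)
    tpr <- upd$tpr; fpr <- upd$fpr
    ll[it + 1] <- consensusLogLik(x, tpr, fpr, prior)
  }
  post <- eStep(x, tpr, fpr, prior)
  new("ConsensusFit",
      tpr = setNames(tpr, colnames(x)), fpr = setNames(fpr, colnames(x)),
      posterior = post, prior = prior, logLik = ll)
}

#' @describeIn fitEM accessor: per-annotator true positive rates.
#' @param fit a [ConsensusFit-class].
#' @export
tpr <- function(fit) fit@tpr

#' @describeIn fitEM accessor: per-annotator false positive rates.
#' @export
fpr <- function(fit) fit@fpr

#' @describeIn fitEM accessor: per-cluster posterior probability of a true spot.
#' @export
posteriorProb <- function(fit) fit@posterior

setMethod("show", "ConsensusFit", function(object) {
  cat(sprintf("ConsensusFit: %d clusters, %d annotators, %d EM iterations\n",
              length(object@posterior), length(object@tpr),
              length(object@logLik) - 1L))
  cat("  TPR:", paste(sprintf("%.3f", object@tpr), collapse = " "), "\n")
  cat("  FPR:", paste(sprintf("%.3f", object@fpr), collapse = " "), "\n")
  cat(sprintf("  logLik: %.2f -> %.2f\n", object@logLik[1],
              object@logLik[length(object@logLik)]))
})

#' Extract consensus spots
#'
#' Retains clusters whose posterior probability exceeds `threshold`
#' (default 0.9); the consensus coordinate is the cluster centroid.
#'
#' @param clusters a `"DetectionClusters"` object.
#' @param posterior per-cluster posteriors (e.g. `posteriorProb(fit)`).
#' @param threshold retention threshold in \[0, 1\] (strict inequality).
#' @return data.frame with `row`, `col`, `p_tp`.
#' @export
extractConsensus <- function(clusters, posterior, threshold = 0.9) {
  .stopifnot2(threshold >= 0 && threshold <= 1, "threshold must lie in [0, 1]")
  .stopifnot2(length(posterior) == nrow(clusters$centroids),
              "posterior length must match cluster count")
  keep <- posterior > threshold
  data.frame(row = clusters$centroids$row[keep],
             col = clusters$centroids$col[keep],
             p_tp = posterior[keep])
}
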