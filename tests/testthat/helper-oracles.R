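# Independent brute-force oracles and small fixture builders shared across
# the suite. These deliberately avoid the package's vectorized code paths.

# render one isotropic Gaussian directly from its formula
renderGauss <- function(shape, r0, c0, A, s, background = 0) {
  img <- matrix(background, shape[1], shape[2])
  for (r in seq_len(shape[1]))
    for (c in seq_len(shape[2]))
      img[r, c] <- img[r, c] + A * exp(-((r - r0)^2 + (c - c0)^2) / (2 * s^2))
  img
}

# exhaustive union-find connected components on a point set
unionFindClusters <- function(pts, radius) {
  n <- nrow(pts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && sqrt((pts$row[i] - pts$row[j])^2 +
                      (pts$col[i] - pts$col[j])^2) <= radius) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, 1L)
}

# exhaustive mutual-nearest-neighbor matcher
mutualNNOracle <- function(pred, truth, threshold) {
  np <- nrow(pred); nt <- nrow(truth)
  if (np == 0 || nt == 0) return(matrix(numeric(0), 0, 2))
  pairs <- NULL
  for (i in seq_len(np)) {
    di <- sqrt((truth$row - pred$row[i])^2 + (truth$col - pred$col[i])^2)
    j <- which.min(di)
    dj <- sqrt((pred$row - truth$row[j])^2 + (pred$col - truth$col[j])^2)
    if (which.min(dj) == i && di[j] <= threshold) pairs <- rbind(pairs, c(i, j))
  }
  if (is.null(pairs)) matrix(numeric(0), 0, 2) else pairs
}

# random screened annotation set for clustering tests
randomAnnotations <- function(n, annotators, extent = 40, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(row = runif(n, 1, extent), col = runif(n, 1, extent),
             annotator = sample(annotators, n, replace = TRUE))
}

# ideal SpotPrediction built from targets (probability = one-hot image,
# regression = target offsets)
idealPrediction <- function(targets) {
  new("SpotPrediction", probability = targets$classification,
      dy = targets$dy, dx = targets$dx)
}

# spots on a jittered grid with guaranteed separation
gridSpots <- function(shape, spacing = 5, jitter = 0.45, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rs <- seq(4, shape[1] - 4, by = spacing)
  cs <- seq(4, shape[2] - 4, by = spacing)
  g <- expand.grid(row = rs, col = cs)
  keep <- sample(nrow(g), min(nrow(g), 25))
  data.frame(row = g$row[keep] + runif(length(keep), -jitter, jitter),
             col = g$col[keep] + runif(length(keep), -jitter, jitter))
}

# full clustering oracle including the screening rule: connected components
# by radius, then per component keep each annotator's member closest to the
# component centroid and split the rest into singletons
clusterOracle <- function(pts, radius) {
  comp <- unionFindClusters(pts, radius)
  out <- comp
  nextLab <- max(comp) + 1L
  for (k in unique(comp)) {
    idx <- which(comp == k)
    cen <- c(mean(pts$row[idx]), mean(pts$col[idx]))
    for (a in unique(pts$annotator[idx])) {
      ai <- idx[pts$annotator[idx] == a]
      if (length(ai) < 2) next
      dd <- (pts$row[ai] - cen[1])^2 + (pts$col[ai] - cen[2])^2
      keep <- ai[which.min(dd)]
      for (s in setdiff(ai, keep)) { out[s] <- nextLab; nextLab <- nextLab + 1L }
    }
  }
  out
}

# partitions agree iff they induce the same co-membership relation
samePartition <- function(a, b) identical(outer(a, a, "=="), outer(b, b, "=="))
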