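# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals.

# minimum Chebyshev distance between the pixel sets of every label pair;
# edge iff <= 2*expandPx (expandPx > 0) or <= 1 (expandPx == 0)
bruteForceAdjacency <- function(mask, expandPx = 1) {
  D <- if (expandPx > 0) 2 * expandPx else 1
  labs <- sort(unique(mask[mask > 0]))
  coords <- lapply(labs, function(l) which(mask == l, arr.ind = TRUE))
  edges <- matrix(integer(0), 0, 2)
  if (length(labs) >= 2) {
    for (i in 2:length(labs)) for (j in 1:(i - 1)) {
      A <- coords[[i]]; B <- coords[[j]]
      cheb <- pmax(abs(outer(A[, 1], B[, 1], "-")),
                   abs(outer(A[, 2], B[, 2], "-")))
      if (min(cheb) <= D)
        edges <- rbind(edges, c(labs[j], labs[i]))
    }
  }
  if (nrow(edges))
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  storage.mode(edges) <- "integer"
  edges
}

# two-pass mean/covariance Pearson
bruteForcePearson <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  ma <- sum(a) / length(a); mb <- sum(b) / length(b)
  sum((a - ma) * (b - mb)) /
    sqrt(sum((a - ma)^2) * sum((b - mb)^2))
}

# one-way ANOVA F from raw sums of squares
bruteForceAnovaF <- function(groups) {
  v <- unlist(groups); gm <- mean(v)
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - gm)^2, 1))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 1))
  k <- length(groups); N <- length(v)
  (ssb / (k - 1)) / (ssw / (N - k))
}

# paint a hard-edged disk into a matrix (same pixel-center convention the
# generator documents: inside iff distance < r)
paintTestDisk <- function(img, cy, cx, r, value = 1) {
  h <- nrow(img); w <- ncol(img)
  for (y in max(1, floor(cy - r - 1)):min(h, ceiling(cy + r + 1)))
    for (x in max(1, floor(cx - r - 1)):min(w, ceiling(cx + r + 1)))
      if ((y - cy)^2 + (x - cx)^2 < r^2) img[y, x] <- value
  img
}

# random disjoint label mask: disks stamped sequentially, later labels
# overwrite earlier ones
randomLabelMask <- function(h, w, nLabels, rMax = 6) {
  m <- matrix(0L, h, w)
  for (l in seq_len(nLabels)) {
    m <- paintTestDisk(m, runif(1, 1, h), runif(1, 1, w),
                       runif(1, 1, rMax), l)
  }
  m
}

# a small SceneTruth whose vesicle table is replaced (for hand-built
# geometry oracles)
truthWithVesicles <- function(df, imageShape = c(64L, 64L)) {
  sp <- sceneSpec(NULL, nCells = 1, vesiclesPerCell = 2,
                  imageShape = imageShape, seed = 1)
  tr <- makeScene(sp, "exp1", "toy")
  tr@vesicles <- df
  tr
}
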