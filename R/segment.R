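#' Maximum-intensity projection of a z-stack
#'
#' Collapses a 3-D acquisition to the 2-D analysis plane by taking, for each
#' (y, x) pixel, the maximum intensity across z planes. A 2-D input is
#' treated as a single-plane stack and returned unchanged.
#'
#' @param stack numeric array with dimensions (z, y, x), a list of 2-D
#'   matrices (planes), or a single matrix.
#' @return numeric matrix (y, x).
#' @examples
#' maxProject(array(1:8, c(2, 2, 2)))
#' @export
maxProject <- function(stack) {
  if (is.list(stack)) {
    if (!length(stack)) stop("empty stack")
    stack <- array(unlist(stack),
                   dim = c(nrow(stack[[1]]), ncol(stack[[1]]), length(stack)))
    return(apply(stack, c(1, 2), max))
  }
  if (is.matrix(stack)) return(stack)
  d <- dim(stack)
  if (length(d) != 3L || d[1] < 1L) stop("empty stack")
  apply(stack, c(2, 3), max)
}

## relabel a mask so labels are 1..L contiguous in first-appearance
## (column-major pixel scan) order; deterministic
.relabel <- function(mask) {
  labs <- unique(mask[mask > 0])
  if (!length(labs)) return(matrix(0L, nrow(mask), ncol(mask)))
  lut <- integer(max(labs))
  lut[labs] <- seq_along(labs)
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[mask > 0] <- lut[mask[mask > 0]]
  out
}

## Otsu threshold robust to the [0,1] range requirement of EBImage::otsu
.otsuThreshold <- function(img) {
  rng <- range(img)
  if (diff(rng) <= 0) return(Inf)  # constant image: nothing is foreground
  sc <- (img - rng[1]) / diff(rng)
  t <- EBImage::otsu(EBImage::Image(sc), range = c(0, 1))
  rng[1] + t * diff(rng)
}

#' Segment cells from a nucleus channel (or validate a supplied mask)
#'
#' When \code{suppliedMask} is given it is validated (integer labels, same
#' shape) and returned unchanged, so externally produced cell masks can be
#' injected at this stage. Otherwise nuclei are Otsu-thresholded on the
#' smoothed nucleus channel, hole-filled and size-filtered, and each
#' retained nucleus seeds one cell territory grown by seeded watershed
#' (CellProfiler-style propagation) on the smoothed cytoplasm channel, or on
#' pure geometric distance to the nuclei when no cytoplasm image is given.
#'
#' @param nucleiImg numeric matrix, nucleus channel.
#' @param cytoImg optional numeric matrix guiding the territory boundaries.
#' @param suppliedMask optional precomputed cell label mask (passed through).
#' @param minNucleusArea smallest nucleus retained, in px.
#' @return integer label matrix, one label per cell; an empty (all-zero)
#'   mask with a warning when no nucleus is detected.
#' @export
segmentCells <- function(nucleiImg, cytoImg = NULL, suppliedMask = NULL,
                         minNucleusArea = 50) {
  if (!is.null(suppliedMask)) {
    m <- suppliedMask
    if (!all(dim(m) == dim(nucleiImg)))
      stop("supplied cell mask shape does not match the image")
    if (any(m < 0) || any(m != round(m)))
      stop("supplied cell mask must contain non-negative integer labels")
    storage.mode(m) <- "integer"
    return(m)
  }
  if (any(!is.finite(nucleiImg)) || any(nucleiImg < 0))
    stop("intensities must be finite and non-negative")
  sm <- .blur(nucleiImg, 2)
  thr <- .otsuThreshold(sm)
  fg <- sm > thr
  if (!any(fg)) {
    warning("no nucleus detected; returning an empty cell mask")
    return(matrix(0L, nrow(nucleiImg), ncol(nucleiImg)))
  }
  nuc <- EBImage::bwlabel(EBImage::fillHull(EBImage::Image(fg * 1)))
  nuc <- as.matrix(nuc)
  areas <- tabulate(nuc[nuc > 0])
  keep <- which(areas >= minNucleusArea)
  if (!length(keep)) {
    warning("no nucleus detected; returning an empty cell mask")
    return(matrix(0L, nrow(nucleiImg), ncol(nucleiImg)))
  }
  nuc[!(nuc %in% keep)] <- 0L
  nuc <- .relabel(nuc)
  if (is.null(cytoImg)) {
    # territories by geometric distance to the nearest nucleus
    guide <- matrix(0, nrow(nucleiImg), ncol(nucleiImg))
    lambda <- 1e4
  } else {
    if (!all(dim(cytoImg) == dim(nucleiImg)))
      stop("cytoplasm image shape does not match the nucleus image")
    guide <- .blur(cytoImg, 2)
    lambda <- 1e-3
  }
  cells <- EBImage::propagate(EBImage::Image(guide), EBImage::Image(nuc),
                              lambda = lambda)
  m <- as.matrix(cells)
  storage.mode(m) <- "integer"
  m
}

## scale-normalized Laplacian-of-Gaussian blob response (bright blobs ->
## positive response), evaluated at sigma = r/sqrt(2); one response matrix
## per radius so per-scale maxima survive even when a coarser scale merges
## neighbouring blobs into a single peak
.logResponses <- function(img, radii) {
  lapply(radii, function(r) {
    s <- r / sqrt(2)
    g <- .blur(img, s)
    # discrete Laplacian (4-neighbour), scale-normalized
    lap <- matrix(0, nrow(img), ncol(img))
    h <- nrow(img); w <- ncol(img)
    lap[2:(h - 1), 2:(w - 1)] <-
      g[1:(h - 2), 2:(w - 1)] + g[3:h, 2:(w - 1)] +
      g[2:(h - 1), 1:(w - 2)] + g[2:(h - 1), 3:w] - 4 * g[2:(h - 1), 2:(w - 1)]
    -s^2 * lap
  })
}

## local maxima of img within a (2k+1)^2 window, as a logical matrix;
## grayscale dilation = moving max
.localMaxima <- function(img, k) {
  brush <- EBImage::makeBrush(2L * k + 1L, shape = "box")
  dil <- as.matrix(EBImage::dilate(EBImage::Image(img), brush))
  img >= dil & is.finite(img)
}

#' Detect vesicles by multiscale LoG markers and seeded watershed
#'
#' A weight-free blob detector for roughly circular, diffraction-blurred
#' vesicles. Background is estimated by grayscale morphological opening with
#' a disk of radius four times \code{maxRadiusPx} and subtracted; the
#' foreground is the Otsu threshold of the residual. Scale-normalized
#' Laplacian-of-Gaussian responses over the radius band provide one marker
#' per intensity blob (local maxima above a fixed fraction of the strongest
#' response), and the foreground is split among markers by seeded watershed
#' so touching vesicles receive separate labels. Labels with area below
#' \code{pi * minRadiusPx^2 / 2} are discarded. All thresholds are relative,
#' so the label count is invariant under uniform intensity rescaling.
#'
#' @param vesicleImg numeric matrix, vesicle channel.
#' @param minRadiusPx,maxRadiusPx radius band in pixels (min >= 1).
#' @param markerRelThreshold marker acceptance as a fraction of the maximum
#'   LoG response.
#' @return integer label matrix with contiguous labels 1..L (0 background).
#' @export
detectVesicles <- function(vesicleImg, minRadiusPx = 3, maxRadiusPx = 6,
                           markerRelThreshold = 0.15) {
  stopifnot(minRadiusPx >= 1, maxRadiusPx >= minRadiusPx)
  if (any(!is.finite(vesicleImg)) || any(vesicleImg < 0))
    stop("intensities must be finite and non-negative")
  h <- nrow(vesicleImg); w <- ncol(vesicleImg)
  empty <- matrix(0L, h, w)
  if (diff(range(vesicleImg)) <= 0) return(empty)
  # robust background: grayscale opening with a large disk
  bgBrush <- EBImage::makeBrush(2L * ceiling(4 * maxRadiusPx) + 1L,
                                shape = "disc")
  bg <- as.matrix(EBImage::opening(EBImage::Image(vesicleImg), bgBrush))
  resid <- pmax(vesicleImg - bg, 0)
  if (diff(range(resid)) <= 0) return(empty)
  fg <- resid > .otsuThreshold(resid)
  if (!any(fg)) return(empty)
  radii <- unique(pmax(seq(minRadiusPx, maxRadiusPx, length.out = 3), 1))
  resps <- .logResponses(.blur(resid, 0.5), radii)
  best <- Reduce(pmax, resps)
  mx <- max(best[fg])
  if (!is.finite(mx) || mx <= 0) return(empty)
  # candidate markers: union of per-scale local maxima (a coarse scale can
  # merge two touching blobs into one peak that the fine scale still splits)
  k <- max(1L, ceiling(minRadiusPx / 2))
  cand <- matrix(numeric(0), 0, 3)
  for (resp in resps) {
    pks <- .localMaxima(resp, k) & fg & resp > markerRelThreshold * mx
    if (any(pks)) {
      pi2 <- which(pks, arr.ind = TRUE)
      cand <- rbind(cand, cbind(pi2, best[pks]))
    }
  }
  if (!nrow(cand)) return(empty)
  # greedy non-maximum suppression: strongest response first, fixed
  # column-major tie-break, so one marker per blob and repeat runs are
  # bit-identical. Candidates closer than minSep to a kept marker are
  # absorbed; between minSep and farSep a candidate survives only if the
  # foreground distance transform necks between the two peaks (touching
  # disks pinch at the tangency, whereas duplicate maxima inside a single
  # disk ride over its distance-map summit).
  ord <- order(-cand[, 3], cand[, 2], cand[, 1])
  cand <- cand[ord, , drop = FALSE]
  dm <- as.matrix(EBImage::distmap(EBImage::Image(fg * 1)))
  minSep <- 3
  farSep <- max(minSep, 2 * minRadiusPx)
  neck <- function(p, q) {
    tfrac <- seq(0, 1, length.out = 21)
    ys <- pmin(pmax(round(p[1] + tfrac * (q[1] - p[1])), 1L), h)
    xs <- pmin(pmax(round(p[2] + tfrac * (q[2] - p[2])), 1L), w)
    path <- dm[cbind(ys, xs)]
    ends <- min(dm[p[1], p[2]], dm[q[1], q[2]])
    ends > 0 && min(path[6:16]) < 1.15 * ends
  }
  kept <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(cand))) {
    p <- cand[i, 1:2]
    ok <- TRUE
    if (nrow(kept)) {
      d2 <- (kept[, 1] - p[1])^2 + (kept[, 2] - p[2])^2
      if (any(d2 < minSep^2)) ok <- FALSE
      else {
        near <- which(d2 < farSep^2)
        for (j in near) if (!neck(p, kept[j, ])) { ok <- FALSE; break }
      }
    }
    if (ok) kept <- rbind(kept, p)
  }
  seeds <- matrix(0L, h, w)
  seeds[kept] <- seq_len(nrow(kept))
  labs <- EBImage::propagate(EBImage::Image(-best), EBImage::Image(seeds),
                             mask = EBImage::Image(fg * 1), lambda = 1e-3)
  m <- as.matrix(labs)
  storage.mode(m) <- "integer"
  areas <- tabulate(m[m > 0])
  tooSmall <- which(areas < pi * minRadiusPx^2 / 2)
  if (length(tooSmall)) m[m %in% tooSmall] <- 0L
  .relabel(m)
}

#' Centroids and areas of a label mask
#'
#' @param mask integer label matrix (0 = background).
#' @return data.frame with columns label, centroid_y, centroid_x, area_px.
#' @export
maskObjectTable <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs))
    return(data.frame(label = integer(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), area_px = integer(0)))
  idx <- which(mask > 0, arr.ind = TRUE)
  l <- mask[mask > 0]
  cy <- tapply(idx[, 1], l, mean)
  cx <- tapply(idx[, 2], l, mean)
  ar <- tapply(idx[, 1], l, length)
  data.frame(label = as.integer(names(cy)), centroid_y = as.numeric(cy),
             centroid_x = as.numeric(cx), area_px = as.integer(ar))
}
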