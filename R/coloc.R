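#' Pearson correlation between two channels over a mask
#'
#' Standard product-moment correlation of pixel intensities, restricted to
#' the pixels where \code{mask > 0} (all pixels when \code{mask} is NULL).
#' A channel that is constant on the mask makes the correlation undefined
#' and raises an error rather than returning 0.
#'
#' @param ch1,ch2 numeric matrices of the same shape.
#' @param mask optional label/binary matrix selecting the region of
#'   interest.
#' @return correlation coefficient in [-1, 1].
#' @examples
#' pearsonR(matrix(1:4, 2), matrix(c(2, 1, 4, 3), 2))
#' @export
pearsonR <- function(ch1, ch2, mask = NULL) {
  if (!all(dim(ch1) == dim(ch2)))
    stop("channels must have the same shape")
  sel <- if (is.null(mask)) rep(TRUE, length(ch1)) else {
    if (!all(dim(mask) == dim(ch1))) stop("mask shape mismatch")
    as.vector(mask > 0)
  }
  a <- as.vector(ch1)[sel]
  b <- as.vector(ch2)[sel]
  if (length(a) < 2L) stop("need at least 2 pixels in the mask")
  if (var(a) == 0 || var(b) == 0)
    stop("undefined correlation: a channel is constant on the mask")
  cor(a, b)
}

## orthogonal (major-axis) regression b ~ a: minimizes perpendicular
## distances; slope sign follows the covariance
.orthRegression <- function(a, b) {
  sxx <- var(a); syy <- var(b); sxy <- cov(a, b)
  if (sxx == 0 || syy == 0) stop("degenerate regression: zero variance")
  slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  if (sxy == 0) slope <- sqrt(syy / sxx)
  list(a = slope, b = mean(b) - slope * mean(a))
}

#' Costes-style auto-thresholded Pearson colocalization
#'
#' Emulates the automatic-threshold colocalization procedure: channel 2 is
#' regressed on channel 1 by orthogonal regression (ch2 = a*ch1 + b); a
#' candidate threshold t1 walks downward from max(ch1) in steps of one
#' quantization level (integer data) or (max-min)/256 (float data), with
#' t2 = a*t1 + b; the walk stops at the largest t1 for which the Pearson
#' correlation of the pixels below both thresholds is <= 0. The reported
#' thresholded coefficient is the Pearson correlation over pixels above
#' threshold in either channel. If no candidate satisfies the stopping rule
#' the thresholds are reported at the minimum with \code{exhausted = TRUE}.
#'
#' @param ch1,ch2 numeric matrices of the same shape.
#' @param mask optional region-of-interest mask (label or binary).
#' @return list with \code{r_pearson} (plain masked Pearson),
#'   \code{r_above_threshold}, thresholds \code{t1}, \code{t2},
#'   \code{n_pixels_used} (pixels above threshold), \code{n_mask_pixels}
#'   and \code{exhausted}.
#' @export
costesThresholdedPearson <- function(ch1, ch2, mask = NULL) {
  rPlain <- pearsonR(ch1, ch2, mask)
  sel <- if (is.null(mask)) rep(TRUE, length(ch1)) else as.vector(mask > 0)
  a <- as.vector(ch1)[sel]
  b <- as.vector(ch2)[sel]
  fit <- .orthRegression(a, b)
  isInt <- all(a == round(a))
  step <- if (isInt) 1 else diff(range(a)) / 256
  if (step <= 0) stop("degenerate regression: zero variance")
  cand <- seq(max(a), min(a), by = -step)
  t1 <- min(a); exhausted <- TRUE
  for (t in cand) {
    t2 <- fit$a * t + fit$b
    below <- a < t & b < t2
    if (sum(below) < 2L) next
    if (var(a[below]) == 0 || var(b[below]) == 0) next
    if (cor(a[below], b[below]) <= 0) {
      t1 <- t; exhausted <- FALSE
      break
    }
  }
  t2 <- fit$a * t1 + fit$b
  above <- a > t1 | b > t2
  rAbove <- if (sum(above) >= 2L && var(a[above]) > 0 && var(b[above]) > 0)
    cor(a[above], b[above]) else NA_real_
  if (exhausted)
    warning("threshold search exhausted all candidates; reporting minimum")
  list(r_pearson = rPlain, r_above_threshold = rAbove, t1 = t1, t2 = t2,
       n_pixels_used = sum(above), n_mask_pixels = length(a),
       exhausted = exhausted)
}

#' Per-cell colocalization table
#'
#' Applies [costesThresholdedPearson()] within each cell of a label mask
#' (or the whole image when no mask is given), one row per region of
#' interest.
#'
#' @param ch1,ch2 numeric matrices of the same shape.
#' @param cellMask optional cell label matrix; rows are produced per label.
#' @return data.frame with columns cell, r, r_thresh, t1, t2, n_pixels.
#' @export
colocTable <- function(ch1, ch2, cellMask = NULL) {
  if (is.null(cellMask)) {
    res <- costesThresholdedPearson(ch1, ch2)
    return(data.frame(cell = 0L, r = res$r_pearson,
                      r_thresh = res$r_above_threshold, t1 = res$t1,
                      t2 = res$t2, n_pixels = res$n_pixels_used))
  }
  labs <- sort(unique(cellMask[cellMask > 0]))
  out <- lapply(labs, function(l) {
    res <- tryCatch(costesThresholdedPearson(ch1, ch2, cellMask == l),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    data.frame(cell = l, r = res$r_pearson, r_thresh = res$r_above_threshold,
               t1 = res$t1, t2 = res$t2, n_pixels = res$n_pixels_used)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(cell = integer(0), r = numeric(0),
                      r_thresh = numeric(0), t1 = numeric(0), t2 = numeric(0),
                      n_pixels = integer(0)))
  do.call(rbind, out)
}
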