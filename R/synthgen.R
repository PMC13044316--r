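#' Construct a SceneSpec, optionally from a named preset
#'
#' The two presets mirror the two spatial regimes a clustering experiment
#' contrasts. \code{"dispersed"} emulates untreated control cells: most
#' vesicles isolated (boundary gap >= \code{minIsolatedGap}), with an
#' incidental-contact component of touching pairs calibrated to a
#' ground-truth contact fraction of 0.4. \code{"clustered"} emulates the
#' perinuclear-clustering condition (GSK3 inhibition / constitutively
#' unphosphorylatable reporter): 70 percent of vesicles in touching chains
#' of four placed near the nucleus, ground-truth contact fraction 0.7.
#'
#' Defaults not fixed by either regime (field 512x512 px, 40 vesicles of
#' radius 3-5 px per cell) are engineering choices documented in the
#' methods vignette.
#'
#' @param preset "dispersed", "clustered", or NULL to start from the
#'   dispersed geometry with no contacts (clusteredFraction 0).
#' @param ... named overrides for any \linkS4class{SceneSpec} slot, e.g.
#'   \code{seed}, \code{nCells}, \code{clusteredFraction}.
#' @return a validated \linkS4class{SceneSpec}.
#' @examples
#' sceneSpec("clustered", nCells = 2, seed = 7)
#' @export
sceneSpec <- function(preset = NULL, ...) {
  base <- list(
    imageShape = c(512L, 512L),
    nCells = 5L,
    vesiclesPerCell = 40L,
    radiusRange = c(3, 5),
    clusteredFraction = 0,
    chainSize = 2L,
    minIsolatedGap = 6,
    perinuclearBias = FALSE,
    psfSigma = 1,
    photonScale = 50,
    readNoiseSd = 0.02,
    backgroundLevel = 0.05,
    peakIntensity = 1,
    seed = 1L
  )
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("dispersed", "clustered"))
    if (preset == "dispersed") {
      base$clusteredFraction <- 0.4
      base$chainSize <- 2L
      base$perinuclearBias <- FALSE
    } else {
      base$clusteredFraction <- 0.7
      base$chainSize <- 4L
      base$perinuclearBias <- TRUE
    }
  }
  ov <- list(...)
  unknown <- setdiff(names(ov), names(base))
  if (length(unknown))
    stop("unknown SceneSpec parameter(s): ", paste(unknown, collapse = ", "))
  base[names(ov)] <- ov
  new("SceneSpec",
      imageShape = as.integer(base$imageShape),
      nCells = as.integer(base$nCells),
      vesiclesPerCell = as.integer(base$vesiclesPerCell),
      radiusRange = as.numeric(base$radiusRange),
      clusteredFraction = as.numeric(base$clusteredFraction),
      chainSize = as.integer(base$chainSize),
      minIsolatedGap = as.numeric(base$minIsolatedGap),
      perinuclearBias = as.logical(base$perinuclearBias),
      psfSigma = as.numeric(base$psfSigma),
      photonScale = as.numeric(base$photonScale),
      readNoiseSd = as.numeric(base$readNoiseSd),
      backgroundLevel = as.numeric(base$backgroundLevel),
      peakIntensity = as.numeric(base$peakIntensity),
      seed = as.integer(base$seed))
}

## rasterize a disk into an integer label matrix (y,x), pixel centers at
## integer coordinates; pixel in disk iff distance from center < r, so the
## pixel area tracks pi*r^2
.paintDisk <- function(mask, cy, cx, r, label) {
  h <- nrow(mask); w <- ncol(mask)
  y0 <- max(1L, floor(cy - r - 1)); y1 <- min(h, ceiling(cy + r + 1))
  x0 <- max(1L, floor(cx - r - 1)); x1 <- min(w, ceiling(cx + r + 1))
  ys <- y0:y1; xs <- x0:x1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, "+")
  sub <- mask[ys, xs, drop = FALSE]
  sub[d2 < r^2] <- label
  mask[ys, xs] <- sub
  mask
}

## star-convex cell blob: boundary radius rho(theta) piecewise-linear over
## control angles; returns the radius function and a rasterizer
.cellBlob <- function(cy, cx, R, nCtrl = 14L) {
  wig <- runif(nCtrl, 0.88, 1.12)
  wig <- (wig + c(wig[-1], wig[1]) + c(wig[nCtrl], wig[-nCtrl])) / 3  # smooth
  th <- seq(0, 2 * pi, length.out = nCtrl + 1L)[-(nCtrl + 1L)]
  rho <- function(theta) {
    theta <- theta %% (2 * pi)
    i <- pmin(findInterval(theta, th), nCtrl)
    j <- i %% nCtrl + 1L
    t0 <- th[i]
    frac <- (theta - t0) / (2 * pi / nCtrl)
    R * (wig[i] * (1 - frac) + wig[j] * frac)
  }
  list(cy = cy, cx = cx, R = R, rho = rho,
       polygon = cbind(y = cy + R * wig * sin(th), x = cx + R * wig * cos(th)))
}

.insideBlob <- function(blob, y, x, margin = 0) {
  dy <- y - blob$cy; dx <- x - blob$cx
  d <- sqrt(dy^2 + dx^2)
  d <= blob$rho(atan2(dy, dx)) - margin
}

.paintBlob <- function(mask, blob, label) {
  h <- nrow(mask); w <- ncol(mask)
  Rmax <- blob$R * 1.15
  y0 <- max(1L, floor(blob$cy - Rmax)); y1 <- min(h, ceiling(blob$cy + Rmax))
  x0 <- max(1L, floor(blob$cx - Rmax)); x1 <- min(w, ceiling(blob$cx + Rmax))
  ys <- y0:y1; xs <- x0:x1
  g <- expand.grid(y = ys, x = xs)
  inside <- .insideBlob(blob, g$y, g$x)
  sub <- mask[ys, xs, drop = FALSE]
  sub[matrix(inside, nrow = length(ys))] <- label
  mask[ys, xs] <- sub
  mask
}

## chain partition honoring clusteredFraction: chains of chainSize, the
## remainder merged into the last chain (never a chain of 1)
.chainSizes <- function(n, fraction, chainSize) {
  nChain <- round(fraction * n)
  if (nChain == 1L) nChain <- 2L
  if (nChain < 2L) return(integer(0))
  sizes <- rep(chainSize, nChain %/% chainSize)
  rem <- nChain %% chainSize
  if (rem == 1L && length(sizes)) sizes[length(sizes)] <- sizes[length(sizes)] + 1L
  else if (rem >= 2L) sizes <- c(sizes, rem)
  else if (rem == 1L) sizes <- 2L  # nChain < chainSize
  sizes
}

## place vesicles for one cell; placed disks from other cells are passed so
## the isolation gap holds field-wide
.placeVesicles <- function(blob, nucleus, spec, existing, firstLabel) {
  n <- spec@vesiclesPerCell
  gap <- spec@minIsolatedGap
  sizes <- .chainSizes(n, spec@clusteredFraction, spec@chainSize)
  nIso <- n - sum(sizes)
  if (nIso < 0) stop("clusteredFraction/chainSize exceed vesiclesPerCell")
  radii <- runif(n, spec@radiusRange[1], spec@radiusRange[2])
  placed <- data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                       radius = numeric(0), chain = integer(0))
  sep <- function(y, x, r, others, extra) {
    # TRUE if (y,x,r) keeps boundary gap >= extra to every disk in others
    if (!nrow(others)) return(TRUE)
    all(sqrt((others$y - y)^2 + (others$x - x)^2) >= others$radius + r + extra)
  }
  inCell <- function(y, x, r) .insideBlob(blob, y, x, margin = r + 1)
  randPoint <- function(perinuclear, widen = 0) {
    if (perinuclear) {
      # chain seeds hug the nucleus; under congestion the annulus widens
      # gradually so placement terminates whenever it is feasible at all
      reach <- min((0.3 + widen) * blob$R, blob$R)
      d <- runif(1, 0, reach) + nucleus$radius * runif(1, 0.2, 0.9)
      a <- runif(1, 0, 2 * pi)
      c(nucleus$cy + d * sin(a), nucleus$cx + d * cos(a))
    } else {
      a <- runif(1, 0, 2 * pi)
      d <- blob$R * sqrt(runif(1))
      c(blob$cy + d * sin(a), blob$cx + d * cos(a))
    }
  }
  vi <- 1L
  chainId <- 0L
  maxTries <- 2000L
  for (len in sizes) {
    chainId <- chainId + 1L
    rs <- radii[vi:(vi + len - 1L)]
    done <- FALSE
    for (restart in seq_len(120L)) {
      pts <- matrix(NA_real_, len, 2)
      ok <- TRUE
      for (tries in seq_len(maxTries)) {
        p <- randPoint(spec@perinuclearBias, widen = 0.02 * max(0, restart - 20L))
        nonchain <- rbind(existing, placed[, names(existing)])
        if (inCell(p[1], p[2], rs[1]) && sep(p[1], p[2], rs[1], nonchain, gap)) {
          pts[1, ] <- p; break
        }
        if (tries == maxTries) ok <- FALSE
      }
      if (ok && len > 1L) {
        ang <- runif(1, 0, 2 * pi)
        for (k in 2:len) {
          found <- FALSE
          for (tries in seq_len(200L)) {
            a <- if (k == 2) runif(1, 0, 2 * pi) else ang + runif(1, -pi / 3, pi / 3)
            d <- rs[k - 1] + rs[k]  # boundary gap exactly 0
            p <- pts[k - 1, ] + d * c(sin(a), cos(a))
            nonchain <- rbind(existing, placed[, names(existing)])
            prior <- pts[seq_len(k - 2L), , drop = FALSE]
            okPrior <- !nrow(prior) ||
              all(sqrt((prior[, 1] - p[1])^2 + (prior[, 2] - p[2])^2) >=
                    rs[seq_len(k - 2L)] + rs[k] - 1)  # overlap capped at 1 px
            if (inCell(p[1], p[2], rs[k]) &&
                sep(p[1], p[2], rs[k], nonchain, gap) && okPrior) {
              pts[k, ] <- p; ang <- a; found <- TRUE; break
            }
          }
          if (!found) { ok <- FALSE; break }
        }
      }
      if (ok) { done <- TRUE; break }
    }
    if (!done)
      stop("placement infeasible: cannot fit a chain of ", len,
           " vesicles in cell at (", round(blob$cy), ",", round(blob$cx), ")")
    placed <- rbind(placed, data.frame(
      label = firstLabel + vi - 1L + seq_len(len) - 1L,
      y = pts[, 1], x = pts[, 2], radius = rs, chain = chainId))
    vi <- vi + len
  }
  for (k in seq_len(nIso)) {
    r <- radii[vi]
    found <- FALSE
    for (tries in seq_len(maxTries)) {
      p <- randPoint(FALSE)
      nonchain <- rbind(existing, placed[, names(existing)])
      if (inCell(p[1], p[2], r) && sep(p[1], p[2], r, nonchain, gap)) {
        placed <- rbind(placed, data.frame(
          label = firstLabel + vi - 1L, y = p[1], x = p[2],
          radius = r, chain = NA_integer_))
        found <- TRUE; break
      }
    }
    if (!found)
      stop("placement infeasible: too many isolated vesicles for the cell ",
           "area at minIsolatedGap = ", gap)
    vi <- vi + 1L
  }
  placed
}

#' Generate the ground truth of a synthetic field
#'
#' Lays out \code{nCells} star-convex cell blobs on a jittered grid, one
#' nucleus disk per cell, and places vesicle disks inside each cell: a
#' calibrated fraction in touching chains (consecutive members at center
#' distance exactly the sum of their radii, i.e. boundary gap 0) and the
#' rest isolated with boundary gap at least \code{minIsolatedGap} to every
#' other vesicle. Placement uses rejection sampling and raises a
#' "placement infeasible" error rather than silently dropping vesicles.
#' Identical specs (including seed) give bit-identical output.
#'
#' @param spec a \linkS4class{SceneSpec}.
#' @param experimentId experiment (replicate batch) tag, recorded in truth.
#' @param conditionTag condition name carried into downstream tables.
#' @return a \linkS4class{SceneTruth} with ground-truth label masks.
#' @examples
#' tr <- makeScene(sceneSpec("clustered", nCells = 1, vesiclesPerCell = 12,
#'                           imageShape = c(192L, 192L), seed = 3))
#' truthContactFraction(tr)
#' @export
makeScene <- function(spec, experimentId = "exp1", conditionTag = "condition") {
  validObject(spec)
  withr::with_seed(spec@seed, {
    h <- spec@imageShape[1]; w <- spec@imageShape[2]
    k <- spec@nCells
    # near-square grid boxes so cell size does not collapse for small k
    nRow <- max(1L, min(k, as.integer(round(sqrt(k * h / w)))))
    nCol <- ceiling(k / nRow)
    boxH <- h / nRow; boxW <- w / nCol
    R <- 0.41 * min(boxH, boxW)
    blobs <- vector("list", k)
    cellDf <- data.frame(cell = integer(0), cy = numeric(0), cx = numeric(0),
                         radius = numeric(0))
    nucDf <- cellDf
    idx <- 0L
    for (i in seq_len(nRow)) for (j in seq_len(nCol)) {
      if (idx >= k) break
      idx <- idx + 1L
      cy <- (i - 0.5) * boxH + runif(1, -0.01, 0.01) * boxH
      cx <- (j - 0.5) * boxW + runif(1, -0.01, 0.01) * boxW
      blobs[[idx]] <- .cellBlob(cy, cx, R)
      cellDf <- rbind(cellDf, data.frame(cell = idx, cy = cy, cx = cx, radius = R))
      nr <- 0.22 * R
      nucDf <- rbind(nucDf, data.frame(
        cell = idx, cy = cy + runif(1, -0.05, 0.05) * R,
        cx = cx + runif(1, -0.05, 0.05) * R, radius = nr))
    }
    ves <- data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                      radius = numeric(0), cell = integer(0), chain = integer(0))
    for (ci in seq_len(k)) {
      ex <- ves[, c("label", "y", "x", "radius")]
      pl <- .placeVesicles(blobs[[ci]], nucDf[ci, ], spec,
                           existing = ex, firstLabel = nrow(ves) + 1L)
      pl$cell <- ci
      # chain ids globally unique across cells
      pl$chain <- ifelse(is.na(pl$chain), NA_integer_,
                         pl$chain + ci * 1000L)
      ves <- rbind(ves, pl[, names(ves)])
    }
    cellMask <- matrix(0L, h, w)
    nucMask <- matrix(0L, h, w)
    vesMask <- matrix(0L, h, w)
    for (ci in seq_len(k)) {
      cellMask <- .paintBlob(cellMask, blobs[[ci]], ci)
      nucMask <- .paintDisk(nucMask, nucDf$cy[ci], nucDf$cx[ci],
                            nucDf$radius[ci], ci)
    }
    for (i in seq_len(nrow(ves)))
      vesMask <- .paintDisk(vesMask, ves$y[i], ves$x[i], ves$radius[i],
                            ves$label[i])
    new("SceneTruth",
        vesicles = ves, cells = cellDf,
        polygons = lapply(blobs, `[[`, "polygon"),
        nuclei = nucDf,
        masks = list(cells = cellMask, nuclei = nucMask, vesicles = vesMask),
        imageShape = spec@imageShape,
        condition = conditionTag, experiment = experimentId, spec = spec)
  })
}

## noiseless structure images (background + peak * disk union), pre-PSF
.sceneStructure <- function(truth, spec = truth@spec) {
  h <- truth@imageShape[1]; w <- truth@imageShape[2]
  vs <- matrix(0L, h, w)
  for (i in seq_len(nrow(truth@vesicles)))
    vs <- .paintDisk(vs, truth@vesicles$y[i], truth@vesicles$x[i],
                     truth@vesicles$radius[i], 1L)
  list(nuclei = spec@backgroundLevel +
         0.8 * spec@peakIntensity * (truth@masks$nuclei > 0),
       vesicles = spec@backgroundLevel + spec@peakIntensity * (vs > 0))
}

.blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  as.matrix(EBImage::gblur(img, sigma = sigma))
}

.cameraNoise <- function(img, photonScale, readNoiseSd) {
  if (photonScale > 0)
    img <- matrix(rpois(length(img), img * photonScale) / photonScale,
                  nrow(img), ncol(img))
  if (readNoiseSd > 0)
    img <- img + matrix(rnorm(length(img), 0, readNoiseSd),
                        nrow(img), ncol(img))
  pmax(img, 0)
}

#' Render a scene into nucleus and vesicle channel images
#'
#' Each vesicle is drawn as a uniform disk of its true radius at peak
#' intensity over a constant background, convolved with a Gaussian PSF of
#' \code{psfSigma} pixels, then corrupted by Poisson photon noise (at
#' \code{photonScale} photons per intensity unit) and additive Gaussian read
#' noise. The nucleus channel renders nucleus disks the same way. With
#' \code{photonScale = 0} and \code{readNoiseSd = 0} the render is
#' noise-free and deterministic; otherwise the noise is seeded from the
#' spec so identical specs give bit-identical images.
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param spec optics/noise parameters; defaults to the spec the truth was
#'   generated from.
#' @return list of numeric matrices \code{nuclei} and \code{vesicles},
#'   non-negative intensities.
#' @export
renderScene <- function(truth, spec = truth@spec) {
  validObject(spec)
  st <- .sceneStructure(truth, spec)
  out <- lapply(st, .blur, sigma = spec@psfSigma)
  withr::with_seed(spec@seed + 77003L, {
    lapply(out, .cameraNoise, photonScale = spec@photonScale,
           readNoiseSd = spec@readNoiseSd)
  })
}

#' Construct a ColocSpec
#'
#' @param alpha mixing coefficient in [0,1]; the second channel's noiseless
#'   structure is \code{alpha} times the first channel's plus
#'   \code{1 - alpha} times an independent vesicle placement.
#' @param photonScale,readNoiseSd,backgroundLevel camera noise model
#'   (defaults noise-free).
#' @param seed seed for the independent placement and noise.
#' @return a validated \linkS4class{ColocSpec}.
#' @export
colocSpec <- function(alpha, photonScale = 0, readNoiseSd = 0,
                      backgroundLevel = 0.05, seed = 1L) {
  new("ColocSpec", alpha = as.numeric(alpha),
      photonScale = as.numeric(photonScale),
      readNoiseSd = as.numeric(readNoiseSd),
      backgroundLevel = as.numeric(backgroundLevel), seed = as.integer(seed))
}

#' Generate a two-channel pair with a controlled degree of co-occurrence
#'
#' Channel 1 is the noiseless vesicle structure of \code{baseTruth} blurred
#' by its PSF. Channel 2 mixes that structure with an independently placed
#' vesicle structure in the same cells (weight \code{1 - alpha}), so that
#' \code{alpha = 1} gives pixelwise identical noiseless channels and
#' \code{alpha = 0} channels sharing only the background. Both channels are
#' then noise-corrupted per the ColocSpec's camera model (independently).
#'
#' @param baseTruth a \linkS4class{SceneTruth} providing channel 1 and the
#'   cell mask.
#' @param cspec a \linkS4class{ColocSpec}.
#' @return list with matrices \code{ch1}, \code{ch2} and the ground-truth
#'   cell label \code{mask}.
#' @export
makeColocPair <- function(baseTruth, cspec) {
  validObject(cspec)
  spec <- baseTruth@spec
  st1 <- .sceneStructure(baseTruth)$vesicles
  spec2 <- spec
  spec2@seed <- cspec@seed
  # independent placement in the same cell geometry
  truth2 <- withr::with_seed(cspec@seed, {
    ves <- data.frame(label = integer(0), y = numeric(0), x = numeric(0),
                      radius = numeric(0), cell = integer(0),
                      chain = integer(0))
    h <- baseTruth@imageShape[1]; w <- baseTruth@imageShape[2]
    vs <- matrix(0L, h, w)
    for (ci in seq_len(nrow(baseTruth@cells))) {
      blob <- list(cy = baseTruth@cells$cy[ci], cx = baseTruth@cells$cx[ci],
                   R = baseTruth@cells$radius[ci])
      blob$rho <- local({
        Rc <- blob$R
        function(theta) rep(Rc, length(theta))
      })
      pl <- .placeVesicles(blob, baseTruth@nuclei[ci, ], spec2,
                           existing = ves[, c("label", "y", "x", "radius")],
                           firstLabel = nrow(ves) + 1L)
      pl$cell <- ci
      ves <- rbind(ves, pl[, names(ves)])
    }
    for (i in seq_len(nrow(ves)))
      vs <- .paintDisk(vs, ves$y[i], ves$x[i], ves$radius[i], 1L)
    vs
  })
  bg <- cspec@backgroundLevel
  peak <- spec@peakIntensity
  s1 <- bg + peak * ((st1 - spec@backgroundLevel) / spec@peakIntensity)
  s2 <- bg + peak * (cspec@alpha * ((st1 - spec@backgroundLevel) / spec@peakIntensity) +
                       (1 - cspec@alpha) * (truth2 > 0))
  ch1 <- .blur(s1, spec@psfSigma)
  ch2 <- .blur(s2, spec@psfSigma)
  withr::with_seed(cspec@seed + 90001L, {
    ch1 <- .cameraNoise(ch1, cspec@photonScale, cspec@readNoiseSd)
    ch2 <- .cameraNoise(ch2, cspec@photonScale, cspec@readNoiseSd)
  })
  list(ch1 = ch1, ch2 = ch2, mask = baseTruth@masks$cells)
}

#' Ground-truth clustering index from scene geometry
#'
#' The geometric oracle for the clustering index: two vesicle disks i, j of
#' the same cell are in contact iff the distance between their centers is at
#' most \code{r_i + r_j + tolPx}. For each cell with at least two vesicles
#' the index is the proportion of its vesicles with at least one contact
#' partner; cells with fewer than two vesicles are reported with
#' \code{NA} index and \code{defined = FALSE}.
#'
#' The default \code{tolPx = 1} mirrors the 1-pixel grace of the
#' pixel-level adjacency rule used downstream ([buildAdjacency()]).
#'
#' @param truth a \linkS4class{SceneTruth}.
#' @param tolPx contact tolerance in pixels (>= 0).
#' @return data.frame with columns condition, experiment, cell, n_vesicles,
#'   n_contacting, index, defined.
#' @export
truthContactFraction <- function(truth, tolPx = 1) {
  stopifnot(tolPx >= 0)
  v <- truth@vesicles
  cells <- sort(unique(v$cell))
  out <- lapply(cells, function(ci) {
    vi <- v[v$cell == ci, ]
    n <- nrow(vi)
    if (n < 2) {
      return(data.frame(condition = truth@condition,
                        experiment = truth@experiment, cell = ci,
                        n_vesicles = n, n_contacting = NA_integer_,
                        index = NA_real_, defined = FALSE))
    }
    d <- as.matrix(dist(cbind(vi$y, vi$x)))
    rsum <- outer(vi$radius, vi$radius, "+")
    touch <- d <= rsum + tolPx
    diag(touch) <- FALSE
    nc <- sum(rowSums(touch) > 0)
    data.frame(condition = truth@condition, experiment = truth@experiment,
               cell = ci, n_vesicles = n, n_contacting = nc,
               index = nc / n, defined = TRUE)
  })
  do.call(rbind, out)
}
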