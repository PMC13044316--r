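#' @import methods
#' @importFrom stats cor cov dist pf pt rnorm rpois runif rchisq sd var aov TukeyHSD setNames aggregate
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

#' Scene specification for the synthetic microscopy generator
#'
#' A \code{SceneSpec} fixes every parameter of a synthetic field of cells:
#' geometry (field size, number of cells, vesicle counts and radii), the
#' contact structure (fraction of vesicles placed into touching chains, chain
#' length, minimum boundary gap for isolated vesicles, perinuclear placement
#' bias), the optics (Gaussian PSF sigma), and the camera noise model
#' (Poisson photon noise at \code{photonScale} photons per intensity unit,
#' additive Gaussian read noise, constant background). All distances are in
#' pixels; intensities are arbitrary units with vesicle peak
#' \code{peakIntensity}.
#'
#' Setting \code{photonScale = 0} and \code{readNoiseSd = 0} disables noise
#' entirely, giving deterministic noise-free renders.
#'
#' @slot imageShape integer(2), (height, width) in pixels.
#' @slot nCells number of cells per field.
#' @slot vesiclesPerCell vesicles placed in each cell.
#' @slot radiusRange numeric(2), min/max vesicle radius in pixels (>= 2).
#' @slot clusteredFraction fraction in [0,1] of vesicles placed into touching
#'   chains; the realized fraction is \code{round(f*n)/n} per cell.
#' @slot chainSize target chain length (>= 2); the last chain absorbs any
#'   remainder so no chain has fewer than 2 members.
#' @slot minIsolatedGap minimum boundary-to-boundary gap (px) between any two
#'   vesicles that are not members of the same chain.
#' @slot perinuclearBias if TRUE, chain seeds are placed within 0.3 cell radii
#'   of the nucleus centroid.
#' @slot psfSigma Gaussian PSF standard deviation in pixels (>= 0).
#' @slot photonScale photons per intensity unit for Poisson noise (0 = off).
#' @slot readNoiseSd additive Gaussian read noise SD (intensity units).
#' @slot backgroundLevel constant background intensity.
#' @slot peakIntensity plateau intensity of a vesicle disk before blurring.
#' @slot seed integer seed; identical specs give bit-identical scenes.
#' @seealso [sceneSpec()] for the user-facing constructor with presets.
#' @exportClass SceneSpec
setClass("SceneSpec", representation(
  imageShape = "integer",
  nCells = "integer",
  vesiclesPerCell = "integer",
  radiusRange = "numeric",
  clusteredFraction = "numeric",
  chainSize = "integer",
  minIsolatedGap = "numeric",
  perinuclearBias = "logical",
  psfSigma = "numeric",
  photonScale = "numeric",
  readNoiseSd = "numeric",
  backgroundLevel = "numeric",
  peakIntensity = "numeric",
  seed = "integer"
))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 32L))
    msg <- c(msg, "imageShape must be two integers >= 32")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be positive")
  if (object@vesiclesPerCell < 1L) msg <- c(msg, "vesiclesPerCell must be positive")
  if (length(object@radiusRange) != 2L || object@radiusRange[1] < 2 ||
      diff(object@radiusRange) < 0)
    msg <- c(msg, "radiusRange must be (min, max) with min >= 2 px")
  if (object@clusteredFraction < 0 || object@clusteredFraction > 1)
    msg <- c(msg, "clusteredFraction must lie in [0, 1]")
  if (object@chainSize < 2L) msg <- c(msg, "chainSize must be >= 2")
  if (object@minIsolatedGap <= 0) msg <- c(msg, "minIsolatedGap must be > 0")
  if (object@psfSigma < 0) msg <- c(msg, "psfSigma must be >= 0")
  if (object@photonScale < 0 || object@readNoiseSd < 0 || object@backgroundLevel < 0)
    msg <- c(msg, "noise parameters must be non-negative")
  if (object@peakIntensity <= 0) msg <- c(msg, "peakIntensity must be positive")
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic field
#'
#' Holds the exact geometry a scene was built from: one row per vesicle
#' (center, radius, owning cell, chain membership), one row per cell (blob
#' polygon and nucleus disk), plus rasterized ground-truth label masks for
#' cells, nuclei and vesicles. Vesicles with \code{chain = NA} are isolated
#' by construction (boundary gap >= \code{minIsolatedGap} to every other
#' vesicle); consecutive members of a chain touch (boundary gap 0, overlap
#' capped at 1 px).
#'
#' @slot vesicles data.frame with columns label, y, x, radius, cell, chain.
#' @slot cells data.frame with columns cell, cy, cx, radius (blob centroid and
#'   mean radius); polygons in \code{polygons}.
#' @slot polygons list of per-cell polygon matrices (columns y, x).
#' @slot nuclei data.frame with columns cell, cy, cx, radius.
#' @slot masks list of integer matrices (cells, nuclei, vesicles); 0 is
#'   background.
#' @slot imageShape integer(2) (height, width).
#' @slot condition condition tag carried to downstream tables.
#' @slot experiment experiment (replicate batch) identifier.
#' @slot spec the \linkS4class{SceneSpec} the truth was generated from.
#' @exportClass SceneTruth
setClass("SceneTruth", representation(
  vesicles = "data.frame",
  cells = "data.frame",
  polygons = "list",
  nuclei = "data.frame",
  masks = "list",
  imageShape = "integer",
  condition = "character",
  experiment = "character",
  spec = "SceneSpec"
))

setValidity("SceneTruth", function(object) {
  v <- object@vesicles
  msg <- character()
  need <- c("label", "y", "x", "radius", "cell", "chain")
  if (!all(need %in% names(v))) return("vesicles lacks required columns")
  if (anyDuplicated(v$label) || any(v$label <= 0))
    msg <- c(msg, "vesicle labels must be unique positive integers")
  if (nrow(v)) {
    sh <- object@imageShape
    if (any(v$y < 1 | v$y > sh[1] | v$x < 1 | v$x > sh[2]))
      msg <- c(msg, "vesicle centers must lie inside the field")
  }
  if (!all(c("cells", "nuclei", "vesicles") %in% names(object@masks)))
    msg <- c(msg, "masks must contain cells, nuclei and vesicles")
  if (length(msg)) msg else TRUE
})

#' Two-channel colocalization scene specification
#'
#' Describes how a second channel is synthesized from a base scene: its
#' noiseless structure is \code{alpha} times the first channel's structure
#' plus \code{1 - alpha} times an independently generated vesicle placement,
#' then corrupted by the same Poisson-Gaussian camera model as
#' \linkS4class{SceneSpec}. \code{alpha = 1} gives perfectly co-occurring
#' signal, \code{alpha = 0} fully independent signal.
#'
#' @slot alpha mixing coefficient in [0, 1].
#' @slot photonScale,readNoiseSd,backgroundLevel camera noise model (0/0
#'   disables noise).
#' @slot seed seed for the independent placement and the noise.
#' @exportClass ColocSpec
setClass("ColocSpec", representation(
  alpha = "numeric",
  photonScale = "numeric",
  readNoiseSd = "numeric",
  backgroundLevel = "numeric",
  seed = "integer"
))

setValidity("ColocSpec", function(object) {
  msg <- character()
  if (object@alpha < 0 || object@alpha > 1) msg <- c(msg, "alpha must lie in [0, 1]")
  if (object@photonScale < 0 || object@readNoiseSd < 0 || object@backgroundLevel < 0)
    msg <- c(msg, "noise parameters must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Undirected vesicle contact graph
#'
#' Nodes are vesicle labels; an edge joins two labels whose pixel supports
#' are in contact under the adjacency rule of [buildAdjacency()]. Edges are
#' stored once with \code{from < to}; the relation is symmetric by
#' construction and self-loops are forbidden.
#'
#' @slot nodes integer vector of vesicle labels present in the mask.
#' @slot edges two-column integer matrix (from, to), from < to.
#' @exportClass ContactGraph
setClass("ContactGraph", representation(
  nodes = "integer",
  edges = "matrix"
))

setValidity("ContactGraph", function(object) {
  e <- object@edges
  msg <- character()
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e)) {
    if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops are not allowed")
    if (any(e[, 1] > e[, 2])) msg <- c(msg, "edges must be stored with from < to")
    if (!all(e %in% object@nodes)) msg <- c(msg, "edges must reference nodes")
    if (anyDuplicated(paste(e[, 1], e[, 2]))) msg <- c(msg, "duplicate edges")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn SceneSpec-class compact parameter display
#' @param object a \code{SceneSpec}
#' @export
setMethod("show", "SceneSpec", function(object) {
  cat(sprintf(
    "SceneSpec: %dx%d px, %d cell(s) x %d vesicles (r %.1f-%.1f px)\n",
    object@imageShape[1], object@imageShape[2], object@nCells,
    object@vesiclesPerCell, object@radiusRange[1], object@radiusRange[2]))
  cat(sprintf(
    "  clusteredFraction %.2f (chains of %d), minIsolatedGap %.1f px, perinuclear %s\n",
    object@clusteredFraction, object@chainSize, object@minIsolatedGap,
    object@perinuclearBias))
  cat(sprintf(
    "  psfSigma %.2f px; noise: photonScale %.0f, readNoiseSd %.2f, background %.3f; seed %d\n",
    object@psfSigma, object@photonScale, object@readNoiseSd,
    object@backgroundLevel, object@seed))
})

#' @describeIn SceneTruth-class summary display
#' @param object a \code{SceneTruth}
#' @export
setMethod("show", "SceneTruth", function(object) {
  cat(sprintf(
    "SceneTruth [%s / %s]: %d cell(s), %d vesicles (%d in chains) on %dx%d px\n",
    object@condition, object@experiment, nrow(object@cells),
    nrow(object@vesicles), sum(!is.na(object@vesicles$chain)),
    object@imageShape[1], object@imageShape[2]))
})

#' @describeIn ContactGraph-class summary display
#' @param object a \code{ContactGraph}
#' @export
setMethod("show", "ContactGraph", function(object) {
  cat(sprintf("ContactGraph: %d nodes, %d contact edges\n",
              length(object@nodes), nrow(object@edges)))
})

#' Accessors for scene objects
#'
#' \code{vesicleTruth} returns the per-vesicle ground-truth table of a
#' \linkS4class{SceneTruth}; \code{truthMasks} its label masks;
#' \code{contactEdges} and \code{contactNodes} the edge list and node set of
#' a \linkS4class{ContactGraph}.
#'
#' @param x a \code{SceneTruth} or \code{ContactGraph}
#' @return a data.frame, list of matrices, matrix or integer vector.
#' @name accessors
#' @examples
#' tr <- makeScene(sceneSpec("dispersed", nCells = 1, vesiclesPerCell = 8,
#'                           imageShape = c(192L, 192L), seed = 1))
#' head(vesicleTruth(tr))
NULL

#' @rdname accessors
#' @export
vesicleTruth <- function(x) {
  stopifnot(is(x, "SceneTruth"))
  x@vesicles
}

#' @rdname accessors
#' @export
truthMasks <- function(x) {
  stopifnot(is(x, "SceneTruth"))
  x@masks
}

#' @rdname accessors
#' @export
contactEdges <- function(x) {
  stopifnot(is(x, "ContactGraph"))
  x@edges
}

#' @rdname accessors
#' @export
contactNodes <- function(x) {
  stopifnot(is(x, "ContactGraph"))
  x@nodes
}
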