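#' Read a TIFF image or label mask
#'
#' Single-page files return a matrix, multi-page files a list of matrices
#' in page order. \code{kind = "label"} reads integer label masks as
#' stored (16-bit), \code{kind = "intensity"} returns float intensities in
#' [0, 1].
#'
#' @param path TIFF file path.
#' @param kind "intensity" or "label".
#' @return matrix or list of matrices.
#' @export
readImageTiff <- function(path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read image: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (kind == "label"))
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]  # drop extra samples
    if (kind == "label") storage.mode(p) <- "integer"
    p
  })
  if (length(pages) == 1L) pages[[1]] else pages
}

#' Write a TIFF image or label mask
#'
#' Label masks are written as 16-bit unsigned TIFF (lossless for labels up
#' to 65535). Intensity images are written as 32-bit float; the package's
#' intensity convention is the [0, 1] range, and out-of-range images are
#' rescaled by their maximum before writing (segmentation operators use
#' relative thresholds, so results are invariant under this rescaling).
#' A list of matrices is written as a multi-page stack preserving order.
#'
#' @param img matrix or list of matrices.
#' @param path destination path.
#' @param kind "intensity" or "label".
#' @return the path, invisibly.
#' @export
writeImageTiff <- function(img, path, kind = c("intensity", "label")) {
  kind <- match.arg(kind)
  pages <- if (is.list(img)) img else list(img)
  if (kind == "label") {
    pages <- lapply(pages, function(p) {
      if (any(p < 0) || any(p != round(p))) stop("labels must be non-negative integers")
      if (max(p) > 65535L) stop("label overflow: 16-bit TIFF holds labels <= 65535")
      p / 65535
    })
    tiff::writeTIFF(if (length(pages) == 1L) pages[[1]] else pages, path,
                    bits.per.sample = 16L)
  } else {
    pages <- lapply(pages, function(p) {
      mx <- max(p)
      if (mx > 1) p <- p / mx
      pmax(p, 0)
    })
    tiff::writeTIFF(if (length(pages) == 1L) pages[[1]] else pages, path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}

.configTemplate <- function() {
  list(
    seed = 1L,
    experiments = 3L,
    cellsPerExperiment = 30L,
    expandPx = 1L,
    minRadiusPx = 3,
    maxRadiusPx = 6,
    tolPx = 1,
    scene = list(),     # shared SceneSpec overrides (e.g. nCells, imageShape)
    conditions = list(  # name -> preset + per-condition overrides
      list(name = "dispersed", preset = "dispersed"),
      list(name = "clustered", preset = "clustered")
    ),
    stats = list(test = "anova-tukey", control = NULL, level = "cell",
                 seed = 1L, nMc = 1e5),
    logLevel = "info"
  )
}

#' Read and validate a pipeline run configuration
#'
#' The config is a YAML file mirroring the arguments of [runPipeline()];
#' unknown keys are rejected so typos fail loudly, and the file round-trips
#' losslessly through [writeRunConfig()].
#'
#' @param path YAML file path.
#' @return a validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @param cfg a (possibly partial) config list; missing keys take defaults.
#' @export
validateRunConfig <- function(cfg) {
  tpl <- .configTemplate()
  unknown <- setdiff(names(cfg), names(tpl))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$stats)) {
    unknownS <- setdiff(names(cfg$stats), names(tpl$stats))
    if (length(unknownS))
      stop("unknown stats config key(s): ", paste(unknownS, collapse = ", "))
    tpl$stats[names(cfg$stats)] <- cfg$stats
    cfg$stats <- NULL
  }
  tpl[names(cfg)] <- cfg
  if (!length(tpl$conditions)) stop("config needs at least one condition")
  for (cd in tpl$conditions)
    if (is.null(cd$name)) stop("every condition needs a name")
  tpl
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
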