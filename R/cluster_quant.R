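#' Assign vesicles to cells by centroid membership
#'
#' Each vesicle label is assigned to the cell whose mask contains its
#' centroid (rounded to the nearest pixel); a centroid falling on background
#' yields \code{NA} (unassigned), and unassigned vesicles are excluded from
#' the clustering index downstream.
#'
#' @param vesicleMask,cellMask integer label matrices of the same shape.
#' @return data.frame with columns vesicle (label) and cell (label or NA).
#' @export
assignToCells <- function(vesicleMask, cellMask) {
  if (!all(dim(vesicleMask) == dim(cellMask)))
    stop("vesicle and cell masks must have the same shape")
  obj <- maskObjectTable(vesicleMask)
  if (!nrow(obj)) return(data.frame(vesicle = integer(0), cell = integer(0)))
  ry <- pmin(pmax(round(obj$centroid_y), 1L), nrow(cellMask))
  rx <- pmin(pmax(round(obj$centroid_x), 1L), ncol(cellMask))
  cell <- cellMask[cbind(ry, rx)]
  data.frame(vesicle = obj$label,
             cell = ifelse(cell > 0L, cell, NA_integer_))
}

#' Build the vesicle contact graph from a label mask
#'
#' Two labeled objects are in contact (following the "adjacent objects"
#' neighbour rule with a configurable expansion) iff after dilating each
#' object by \code{expandPx} steps of a 3x3 (8-connected) structuring
#' element their supports overlap. Equivalently, an edge joins labels whose
#' minimum Chebyshev distance between pixel sets is at most
#' \code{2 * expandPx} when \code{expandPx > 0}, or at most 1 (plain
#' 8-connected touching, including diagonal corners) when
#' \code{expandPx = 0}. The default \code{expandPx = 1} means "touching or
#' separated by at most one background pixel".
#'
#' @param vesicleMask integer label matrix.
#' @param expandPx object expansion in pixels (>= 0).
#' @return a \linkS4class{ContactGraph}.
#' @examples
#' m <- matrix(0L, 8, 8)
#' m[2, 2:3] <- 1L; m[2, 4] <- 2L; m[6, 6] <- 3L
#' contactEdges(buildAdjacency(m, expandPx = 0))
#' @export
buildAdjacency <- function(vesicleMask, expandPx = 1L) {
  stopifnot(expandPx >= 0)
  D <- if (expandPx > 0) 2L * as.integer(expandPx) else 1L
  h <- nrow(vesicleMask); w <- ncol(vesicleMask)
  nodes <- sort(unique(vesicleMask[vesicleMask > 0]))
  if (length(nodes) < 2L)
    return(new("ContactGraph", nodes = as.integer(nodes),
               edges = matrix(integer(0), 0, 2,
                              dimnames = list(NULL, c("from", "to")))))
  idx <- which(vesicleMask > 0, arr.ind = TRUE)
  labs <- vesicleMask[vesicleMask > 0]
  labAt <- integer(h * w)
  labAt[(idx[, 2] - 1L) * h + idx[, 1]] <- labs
  edges <- vector("list", (2L * D + 1L)^2)
  k <- 0L
  for (dy in -D:D) for (dx in -D:D) {
    if (dy == 0L && dx == 0L) next
    y2 <- idx[, 1] + dy; x2 <- idx[, 2] + dx
    ok <- y2 >= 1L & y2 <= h & x2 >= 1L & x2 <= w
    if (!any(ok)) next
    l2 <- labAt[(x2[ok] - 1L) * h + y2[ok]]
    l1 <- labs[ok]
    hit <- l2 > 0L & l2 != l1
    if (any(hit)) {
      k <- k + 1L
      edges[[k]] <- cbind(pmin(l1[hit], l2[hit]), pmax(l1[hit], l2[hit]))
    }
  }
  e <- if (k) unique(do.call(rbind, edges[seq_len(k)])) else
    matrix(integer(0), 0, 2)
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  storage.mode(e) <- "integer"
  dimnames(e) <- list(NULL, c("from", "to"))
  new("ContactGraph", nodes = as.integer(nodes), edges = e)
}

#' Per-cell clustering index from a contact graph
#'
#' The headline statistic: for each cell, the proportion of its vesicles in
#' direct contact with at least one other vesicle of the same cell. Edges
#' between vesicles assigned to different cells are ignored (a vesicle
#' touching only a neighbouring cell's vesicle counts as non-contacting),
#' and vesicles with no cell assignment are excluded. Cells with fewer than
#' two assigned vesicles get \code{NA} index and \code{defined = FALSE};
#' they are excluded from condition means.
#'
#' @param graph a \linkS4class{ContactGraph} over vesicle labels.
#' @param assignment data.frame from [assignToCells()].
#' @param condition,experiment tags copied into the output rows.
#' @return data.frame with columns condition, experiment, cell, n_vesicles,
#'   n_contacting, index, defined (a per-scene slice of the cluster-index
#'   table).
#' @export
clusteringIndex <- function(graph, assignment,
                            condition = "condition", experiment = "exp1") {
  stopifnot(is(graph, "ContactGraph"))
  if (!all(graph@nodes %in% assignment$vesicle))
    stop("every graph node must appear in the assignment")
  cellOf <- setNames(assignment$cell, assignment$vesicle)
  e <- graph@edges
  if (nrow(e)) {
    c1 <- cellOf[as.character(e[, 1])]
    c2 <- cellOf[as.character(e[, 2])]
    sameCell <- !is.na(c1) & !is.na(c2) & c1 == c2
    e <- e[sameCell, , drop = FALSE]
  }
  contacting <- unique(as.vector(e))
  cells <- sort(unique(assignment$cell[!is.na(assignment$cell)]))
  out <- lapply(cells, function(ci) {
    vs <- assignment$vesicle[!is.na(assignment$cell) & assignment$cell == ci]
    n <- length(vs)
    if (n < 2L)
      return(data.frame(condition = condition, experiment = experiment,
                        cell = ci, n_vesicles = n,
                        n_contacting = NA_integer_, index = NA_real_,
                        defined = FALSE))
    nc <- sum(vs %in% contacting)
    data.frame(condition = condition, experiment = experiment, cell = ci,
               n_vesicles = n, n_contacting = nc, index = nc / n,
               defined = TRUE)
  })
  if (!length(out))
    return(data.frame(condition = character(0), experiment = character(0),
                      cell = integer(0), n_vesicles = integer(0),
                      n_contacting = integer(0), index = numeric(0),
                      defined = logical(0)))
  do.call(rbind, out)
}
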