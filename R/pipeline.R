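.deriveSeed <- function(...) {
  s <- 0
  for (x in list(...)) s <- (s * 97 + as.numeric(x)) %% 2147480000
  as.integer(s) + 1L
}

.logStage <- function(lines, stage, t0, level = "info") {
  msg <- sprintf("[%s] %-10s %.2fs", format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0)
  if (level != "quiet") message(msg)
  c(lines, msg)
}

#' Run the full clustering-index pipeline on synthetic scenes
#'
#' One call wires the whole workflow: for each condition and experiment,
#' generate scenes ([makeScene()]), render them ([renderScene()]), project
#' ([maxProject()]), segment cells and vesicles ([segmentCells()],
#' [detectVesicles()]), assign vesicles to cells ([assignToCells()]), build
#' the contact graph ([buildAdjacency()]) and compute per-cell clustering
#' indices ([clusteringIndex()]); finally the statistics stage compares
#' conditions on the per-cell values (one-way ANOVA with Tukey HSD by
#' default, or Student's t / Dunnett per config). Ground-truth indices
#' ([truthContactFraction()]) are carried alongside for validation.
#'
#' Every random stage is seeded deterministically from the config seed (or
#' the per-condition \code{experimentSeeds}), so identical configs give
#' identical outputs. When \code{outDir} is given, all tables, masks, a
#' manifest and a run log are written there.
#'
#' @param config config list as produced by [validateRunConfig()] /
#'   [readRunConfig()]; partial lists are completed with defaults.
#' @param outDir optional output directory.
#' @param useTruthMasks if TRUE, skip segmentation and use the ground-truth
#'   vesicle/cell masks (isolates the adjacency + index stages).
#' @return list with \code{indexTable} (per-cell indices), \code{truthTable}
#'   (geometric-oracle indices), \code{summary} (superplot summaries at cell
#'   and experiment level), \code{comparisons} (statistics stage) and
#'   \code{manifest}.
#' @export
runPipeline <- function(config = list(), outDir = NULL,
                        useTruthMasks = FALSE) {
  cfg <- validateRunConfig(config)
  t0 <- as.numeric(Sys.time())
  loglines <- character(0)
  quiet <- identical(cfg$logLevel, "quiet")
  lv <- if (quiet) "quiet" else "info"
  idxAll <- list(); truthAll <- list()
  for (cix in seq_along(cfg$conditions)) {
    cd <- cfg$conditions[[cix]]
    ov <- cd; ov$name <- NULL; ov$preset <- NULL; ov$experimentSeeds <- NULL
    sceneArgs <- modifyList(cfg$scene, ov)
    expSeeds <- cd$experimentSeeds
    if (is.null(expSeeds))
      expSeeds <- vapply(seq_len(cfg$experiments), function(e)
        .deriveSeed(cfg$seed, cix, e), 1L)
    for (e in seq_along(expSeeds)) {
      expId <- sprintf("exp%d", e)
      probe <- do.call(sceneSpec, c(list(preset = cd$preset), sceneArgs,
                                    list(seed = 1L)))
      nScenes <- ceiling(cfg$cellsPerExperiment / probe@nCells)
      cellsLeft <- cfg$cellsPerExperiment
      for (s in seq_len(nScenes)) {
        nHere <- min(probe@nCells, cellsLeft)
        cellsLeft <- cellsLeft - nHere
        spec <- do.call(sceneSpec, c(
          list(preset = cd$preset), sceneArgs,
          list(nCells = nHere, seed = .deriveSeed(expSeeds[e], s))))
        truth <- makeScene(spec, experimentId = expId,
                           conditionTag = cd$name)
        tt <- truthContactFraction(truth, tolPx = cfg$tolPx)
        if (useTruthMasks) {
          vesMask <- truth@masks$vesicles
          cellMask <- truth@masks$cells
        } else {
          imgs <- renderScene(truth)
          ves2d <- maxProject(imgs$vesicles)
          cellMask <- segmentCells(imgs$nuclei)
          vesMask <- detectVesicles(ves2d, minRadiusPx = cfg$minRadiusPx,
                                    maxRadiusPx = cfg$maxRadiusPx)
        }
        asg <- assignToCells(vesMask, cellMask)
        graph <- buildAdjacency(vesMask, expandPx = cfg$expandPx)
        idx <- clusteringIndex(graph, asg, condition = cd$name,
                               experiment = expId)
        uid <- function(d) sprintf("s%d_c%d", s, d$cell)
        if (nrow(idx)) idx$cell <- uid(idx)
        if (nrow(tt)) tt$cell <- uid(tt)
        idxAll[[length(idxAll) + 1L]] <- idx
        truthAll[[length(truthAll) + 1L]] <- tt
        if (!is.null(outDir)) {
          dir.create(file.path(outDir, "masks"), recursive = TRUE,
                     showWarnings = FALSE)
          base <- sprintf("%s_%s_s%d", cd$name, expId, s)
          writeImageTiff(vesMask,
                         file.path(outDir, "masks", paste0(base, "_vesicles.tif")),
                         kind = "label")
          writeImageTiff(cellMask,
                         file.path(outDir, "masks", paste0(base, "_cells.tif")),
                         kind = "label")
        }
      }
      loglines <- .logStage(loglines, sprintf("%s/%s", cd$name, expId), t0, lv)
    }
  }
  indexTable <- do.call(rbind, idxAll)
  truthTable <- do.call(rbind, truthAll)
  defined <- indexTable[indexTable$defined, ]
  sp <- data.frame(condition = defined$condition,
                   experiment = defined$experiment, cell = defined$cell,
                   value = defined$index)
  summary <- list(cell = aggregateSuperplot(sp, "cell"),
                  experiment = aggregateSuperplot(sp, "experiment"))
  comparisons <- NULL
  conds <- unique(sp$condition)
  if (length(conds) >= 2) {
    lvl <- cfg$stats$level
    groups <- if (lvl == "experiment") {
      em <- aggregate(value ~ condition + experiment, sp, mean)
      split(em$value, em$condition)
    } else split(sp$value, sp$condition)
    groups <- groups[conds]
    comparisons <- switch(
      cfg$stats$test,
      "t" = studentsT(groups[[1]], groups[[2]], labels = names(groups)[1:2]),
      "anova-tukey" = rbind(oneWayAnova(groups)[, c("test", "pair",
                                                    "statistic", "df", "p",
                                                    "adj_p", "stars",
                                                    "significant")],
                            tukeyHsd(groups)),
      "anova-dunnett" = {
        ctrl <- cfg$stats$control
        if (is.null(ctrl)) ctrl <- names(groups)[1]
        dunnettMC(groups[[ctrl]], groups[names(groups) != ctrl],
                  nMc = cfg$stats$nMc, seed = cfg$stats$seed)
      },
      stop("unknown stats test: ", cfg$stats$test))
    loglines <- .logStage(loglines, "stats", t0, lv)
  }
  manifest <- list(
    package = "vesiclust",
    version = as.character(packageVersion("vesiclust")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config = cfg,
    n_cells_defined = nrow(defined),
    outputs = c("index_table.csv", "truth_table.csv", "comparisons.csv"))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(indexTable, file.path(outDir, "index_table.csv"),
              row.names = FALSE)
    write.csv(truthTable, file.path(outDir, "truth_table.csv"),
              row.names = FALSE)
    if (!is.null(comparisons))
      write.csv(comparisons, file.path(outDir, "comparisons.csv"),
                row.names = FALSE)
    yaml::write_yaml(manifest, file.path(outDir, "manifest.yaml"))
    writeLines(loglines, file.path(outDir, "run.log"))
  }
  list(indexTable = indexTable, truthTable = truthTable, summary = summary,
       comparisons = comparisons, manifest = manifest, log = loglines)
}
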