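test_that("vesicles are assigned to the cell containing their centroid", {
  cells <- matrix(0L, 10, 10)
  cells[, 1:5] <- 1L; cells[, 6:9] <- 2L  # column 10 is background
  ves <- matrix(0L, 10, 10)
  ves[3, 2:3] <- 1L                      # wholly inside cell 1
  ves[6, 5:7] <- 2L                      # straddles; centroid at x=6 -> cell 2
  ves[9, 10] <- 3L                       # centroid on background
  asg <- assignToCells(ves, cells)
  expect_equal(asg$cell[asg$vesicle == 1L], 1L)
  expect_equal(asg$cell[asg$vesicle == 2L], 2L)
  expect_true(is.na(asg$cell[asg$vesicle == 3L]))
})

test_that("adjacency follows the Chebyshev contact rule on a toy grid", {
  m <- matrix(0L, 8, 8)
  m[2, 2:3] <- 1L  # A
  m[2, 4] <- 2L    # B, touching A
  m[6, 6] <- 3L    # C, far away
  g <- buildAdjacency(m, expandPx = 0)
  expect_equal(contactEdges(g), matrix(c(1L, 2L), 1, 2,
                                       dimnames = list(NULL, c("from", "to"))))
  # diagonal corners are adjacent (8-connectivity)
  m2 <- matrix(0L, 4, 4)
  m2[1, 1] <- 1L; m2[2, 2] <- 2L
  expect_equal(nrow(contactEdges(buildAdjacency(m2, expandPx = 0))), 1L)
  # a single label yields no edges
  m3 <- matrix(0L, 4, 4); m3[2, 2] <- 5L
  expect_equal(nrow(contactEdges(buildAdjacency(m3))), 0L)
  # the default grace: one background pixel between objects still connects
  m4 <- matrix(0L, 5, 5)
  m4[3, 1] <- 1L; m4[3, 3] <- 2L
  expect_equal(nrow(contactEdges(buildAdjacency(m4, expandPx = 0))), 0L)
  expect_equal(nrow(contactEdges(buildAdjacency(m4, expandPx = 1))), 1L)
})

test_that("adjacency matches the brute-force Chebyshev oracle", {
  set.seed(21)
  for (rep in 1:25) {
    m <- randomLabelMask(sample(24:64, 1), sample(24:64, 1),
                         nLabels = sample(2:7, 1))
    for (ex in 0:1) {
      got <- contactEdges(buildAdjacency(m, expandPx = ex))
      want <- bruteForceAdjacency(m, expandPx = ex)
      expect_equal(unname(got), unname(want),
                   info = sprintf("rep %d expand %d", rep, ex))
    }
  }
})

test_that("clustering index counts vesicles with intra-cell contacts", {
  m <- matrix(0L, 8, 8)
  m[2, 2:3] <- 1L; m[2, 4] <- 2L; m[6, 6] <- 3L
  asg <- data.frame(vesicle = 1:3, cell = 1L)
  g <- buildAdjacency(m, expandPx = 0)
  out <- clusteringIndex(g, asg)
  expect_equal(out$index, 2 / 3)
  expect_equal(out$n_contacting, 2L)
  # a chain of four touching vesicles: index 1
  m2 <- matrix(0L, 6, 12)
  m2[3, 2:3] <- 1L; m2[3, 4:5] <- 2L; m2[3, 6:7] <- 3L; m2[3, 8:9] <- 4L
  out2 <- clusteringIndex(buildAdjacency(m2, 0),
                          data.frame(vesicle = 1:4, cell = 1L))
  expect_equal(out2$index, 1.0)
  # a cell with a single vesicle is undefined
  out3 <- clusteringIndex(buildAdjacency(m3 <- {
    z <- matrix(0L, 4, 4); z[2, 2] <- 1L; z
  }), data.frame(vesicle = 1L, cell = 1L))
  expect_false(out3$defined)
  expect_true(is.na(out3$index))
})

test_that("inter-cell contacts are discarded", {
  m <- matrix(0L, 6, 6)
  m[3, 2:3] <- 1L; m[3, 4] <- 2L  # touching pair
  # but the two vesicles belong to different cells
  asg <- data.frame(vesicle = 1:2, cell = c(1L, 2L))
  out <- clusteringIndex(buildAdjacency(m, 0), asg)
  expect_true(all(!out$defined))  # each cell has a single vesicle
  # with a second vesicle per cell, the cross-cell edge still counts nothing
  m[5, 2] <- 3L; m[5, 5] <- 4L
  asg <- data.frame(vesicle = 1:4, cell = c(1L, 2L, 1L, 2L))
  out <- clusteringIndex(buildAdjacency(m, 0), asg)
  expect_equal(out$index, c(0, 0))
})

test_that("unassigned vesicles are excluded from the index", {
  m <- matrix(0L, 6, 6)
  m[3, 2:3] <- 1L; m[3, 4] <- 2L; m[5, 2] <- 3L
  asg <- data.frame(vesicle = 1:3, cell = c(1L, NA, 1L))
  out <- clusteringIndex(buildAdjacency(m, 0), asg)
  # vesicle 2 is unassigned: vesicle 1 loses its only partner
  expect_equal(out$index, 0)
  expect_equal(out$n_vesicles, 2L)
})

test_that("contact graph is symmetric and relabeling leaves indices unchanged", {
  set.seed(33)
  m <- randomLabelMask(48, 48, 6)
  g <- buildAdjacency(m, 1)
  e <- contactEdges(g)
  expect_true(all(e[, 1] < e[, 2]))
  # relabel objects and check the index multiset is unchanged
  labs <- sort(unique(m[m > 0]))
  perm <- setNames(sample(100 + seq_along(labs)), labs)
  m2 <- m; m2[m > 0] <- perm[as.character(m[m > 0])]
  asg1 <- data.frame(vesicle = labs, cell = 1L)
  asg2 <- data.frame(vesicle = unname(perm), cell = 1L)
  i1 <- clusteringIndex(buildAdjacency(m, 1), asg1)
  i2 <- clusteringIndex(buildAdjacency(m2, 1), asg2)
  expect_equal(i1$index, i2$index)
})

test_that("index never decreases when an edge is added", {
  asg <- data.frame(vesicle = 1:4, cell = 1L)
  gSmall <- new("ContactGraph", nodes = 1:4,
                edges = matrix(c(1L, 2L), 1, 2))
  gBig <- new("ContactGraph", nodes = 1:4,
              edges = rbind(c(1L, 2L), c(3L, 4L)))
  expect_lte(clusteringIndex(gSmall, asg)$index,
             clusteringIndex(gBig, asg)$index)
})

test_that("pipeline index tracks the geometric oracle on clean renders", {
  diffs <- c()
  for (f in c(0, 0.5, 1)) {
    idxs <- truths <- c()
    for (seed in 1:2) {
      sp <- sceneSpec(NULL, nCells = 1, vesiclesPerCell = 30,
                      clusteredFraction = f, chainSize = 2L, psfSigma = 1,
                      photonScale = 0, readNoiseSd = 0,
                      imageShape = c(256L, 256L), seed = seed)
      tr <- makeScene(sp)
      imgs <- renderScene(tr)
      vm <- detectVesicles(imgs$vesicles, 3, 6)
      cm <- segmentCells(imgs$nuclei)
      idx <- clusteringIndex(buildAdjacency(vm, 1), assignToCells(vm, cm))
      idxs <- c(idxs, idx$index)
      truths <- c(truths, truthContactFraction(tr)$index)
    }
    diffs <- c(diffs, abs(mean(idxs) - mean(truths)))
  }
  expect_true(all(diffs <= 0.05))
})
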