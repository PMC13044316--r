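test_that("geometric contact oracle follows the disk-touch rule", {
  # two disks at center distance exactly r1 + r2 touch; 1 px further they don't
  mk <- function(x2) data.frame(
    label = 1:2, y = c(10, 10), x = c(10, x2), radius = c(2, 2),
    cell = c(1L, 1L), chain = c(NA_integer_, NA_integer_))
  tr <- truthWithVesicles(mk(14))
  expect_equal(truthContactFraction(tr, tolPx = 0)$index, 1.0)
  tr <- truthWithVesicles(mk(15))
  expect_equal(truthContactFraction(tr, tolPx = 0)$index, 0.0)
  # pair + far singleton: 2 of 3 in contact
  tr <- truthWithVesicles(data.frame(
    label = 1:3, y = c(10, 10, 30), x = c(10, 14, 30),
    radius = c(2, 2, 2), cell = 1L, chain = NA_integer_))
  expect_equal(truthContactFraction(tr, tolPx = 0)$index, 2 / 3)
})

test_that("contact oracle flags cells with fewer than two vesicles", {
  tr <- truthWithVesicles(data.frame(
    label = 1L, y = 10, x = 10, radius = 3, cell = 1L, chain = NA_integer_))
  out <- truthContactFraction(tr)
  expect_false(out$defined)
  expect_true(is.na(out$index))
})

test_that("scene construction realizes the requested contact structure", {
  # all isolated: gap construction forbids contacts
  tr <- makeScene(sceneSpec(NULL, nCells = 1, vesiclesPerCell = 3,
                            minIsolatedGap = 6, imageShape = c(128L, 128L),
                            seed = 1))
  v <- vesicleTruth(tr)
  expect_equal(nrow(v), 3L)
  expect_true(all(is.na(v$chain)))
  expect_equal(truthContactFraction(tr)$index, 0.0)
  # one chain of three: everything touches
  tr <- makeScene(sceneSpec(NULL, nCells = 1, vesiclesPerCell = 3,
                            clusteredFraction = 1, chainSize = 3L,
                            imageShape = c(128L, 128L), seed = 1))
  expect_equal(truthContactFraction(tr)$index, 1.0)
  # 7 chains of 4 + 12 isolated out of 40
  tr <- makeScene(sceneSpec(NULL, nCells = 1, vesiclesPerCell = 40,
                            clusteredFraction = 0.7, chainSize = 4L,
                            imageShape = c(256L, 256L), seed = 2))
  v <- vesicleTruth(tr)
  expect_equal(sum(!is.na(v$chain)), 28L)
  expect_equal(length(unique(na.omit(v$chain))), 7L)
  expect_equal(truthContactFraction(tr)$index, 28 / 40)
})

test_that("construction soundness holds across clustered fractions", {
  for (f in c(0, 0.25, 0.5, 0.75, 1)) {
    tr <- makeScene(sceneSpec(NULL, nCells = 1, vesiclesPerCell = 20,
                              clusteredFraction = f, chainSize = 2L,
                              imageShape = c(224L, 224L), seed = 7))
    v <- vesicleTruth(tr)
    expect_equal(truthContactFraction(tr)$index, sum(!is.na(v$chain)) / nrow(v),
                 info = sprintf("fraction %.2f", f))
  }
})

test_that("scene truth invariants hold: gaps, touching chains, containment", {
  tr <- makeScene(sceneSpec("clustered", nCells = 2, vesiclesPerCell = 30,
                            imageShape = c(384L, 384L), seed = 11))
  v <- vesicleTruth(tr)
  expect_false(anyDuplicated(v$label) > 0)
  d <- as.matrix(dist(cbind(v$y, v$x)))
  rsum <- outer(v$radius, v$radius, "+")
  sameChain <- !is.na(outer(v$chain, v$chain, "==")) &
    outer(v$chain, v$chain, "==")
  gap <- d - rsum
  off <- upper.tri(d) & !sameChain
  expect_true(all(gap[off] >= 6 - 1e-9))        # isolation gap
  # every chain member touches its predecessor (gap ~ 0 for some partner)
  for (ch in unique(na.omit(v$chain))) {
    idx <- which(!is.na(v$chain) & v$chain == ch)
    for (i in idx)
      expect_true(min(gap[i, setdiff(idx, i)]) <= 1e-6)
  }
})

test_that("scene generation is bit-identical for a fixed seed", {
  sp <- sceneSpec("clustered", nCells = 1, vesiclesPerCell = 15,
                  imageShape = c(160L, 160L), seed = 5)
  t1 <- makeScene(sp); t2 <- makeScene(sp)
  expect_identical(t1@vesicles, t2@vesicles)
  expect_identical(t1@masks, t2@masks)
  expect_identical(renderScene(t1), renderScene(t2))
})

test_that("infeasible placement errors instead of silently truncating", {
  sp <- sceneSpec(NULL, nCells = 1, vesiclesPerCell = 200,
                  minIsolatedGap = 10, imageShape = c(96L, 96L), seed = 1)
  expect_error(makeScene(sp), "placement infeasible")
})

test_that("rendering without PSF or noise reproduces the truth support", {
  sp <- sceneSpec(NULL, nCells = 1, vesiclesPerCell = 4, psfSigma = 0,
                  photonScale = 0, readNoiseSd = 0, backgroundLevel = 0,
                  imageShape = c(128L, 128L), seed = 3)
  tr <- makeScene(sp)
  img <- renderScene(tr)$vesicles
  expect_identical(img > 0, truthMasks(tr)$vesicles > 0)
  # no vesicles: image is exactly the background
  tr0 <- tr
  tr0@vesicles <- tr@vesicles[0, ]
  sp2 <- sp; sp2@backgroundLevel <- 0.07
  img0 <- renderScene(tr0, sp2)$vesicles
  expect_true(all(img0 == 0.07))
})

test_that("a blurred disk keeps its area under Otsu thresholding", {
  sp <- sceneSpec(NULL, nCells = 1, vesiclesPerCell = 1, psfSigma = 1,
                  radiusRange = c(5, 5), photonScale = 0, readNoiseSd = 0,
                  imageShape = c(128L, 128L), seed = 2)
  tr <- makeScene(sp)
  img <- renderScene(tr)$vesicles
  thr <- EBImage::otsu(EBImage::Image(img / max(img))) * max(img)
  area <- sum(img > thr)
  expect_lt(abs(area - pi * 25) / (pi * 25), 0.15)
})

test_that("noise-free rendering conserves integrated intensity", {
  sp <- sceneSpec(NULL, nCells = 1, vesiclesPerCell = 10, psfSigma = 1.5,
                  photonScale = 0, readNoiseSd = 0, imageShape = c(192L, 192L),
                  seed = 6)
  tr <- makeScene(sp)
  img <- renderScene(tr)$vesicles
  unionArea <- sum(truthMasks(tr)$vesicles > 0)
  total <- sum(img - sp@backgroundLevel)
  expect_lt(abs(total - unionArea * sp@peakIntensity) /
              (unionArea * sp@peakIntensity), 0.005)
})

test_that("contact oracle is symmetric and relabeling-invariant", {
  tr <- makeScene(sceneSpec("dispersed", nCells = 1, vesiclesPerCell = 20,
                            imageShape = c(224L, 224L), seed = 9))
  base <- truthContactFraction(tr)
  perm <- tr
  v <- perm@vesicles
  set.seed(1)
  newLabs <- sample(1000:2000, nrow(v))
  v$label <- newLabs
  perm@vesicles <- v[sample(nrow(v)), ]
  expect_equal(truthContactFraction(perm)$index, base$index)
})

test_that("spec validation rejects out-of-range parameters", {
  expect_error(sceneSpec(NULL, clusteredFraction = 1.2), "clusteredFraction")
  expect_error(sceneSpec(NULL, radiusRange = c(1, 5)), "radiusRange")
  expect_error(sceneSpec(NULL, psfSigma = -1), "psfSigma")
  expect_error(sceneSpec(NULL, readNoiseSd = -0.1), "non-negative")
  expect_error(sceneSpec(NULL, bogus = 1), "unknown")
})
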