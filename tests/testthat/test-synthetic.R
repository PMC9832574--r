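test_that("shape specs reject inconsistent archetypes", {
  expect_error(shapeSpec("bipolar", 6, 3, 30, 2), "exactly 2")
  expect_error(shapeSpec("round", 8, 1, 5, 2), "0 processes")
  expect_error(shapeSpec("round", -1, 0, 0, 0), "somaRadius")
  expect_error(shapeSpec("hypertrophic", 9, 0, 0, 0, branchPoints = 2),
               "at least one process")
})

test_that("rendered disk has the right area and rendering is reproducible", {
  sp <- shapeSpec("round", 8, 0, 0, 0, seed = 3)
  p1 <- renderCell(sp, 0.758)
  expect_lt(abs(sum(p1$mask) * 0.758^2 - pi * 64) / (pi * 64), 0.05)
  p2 <- renderCell(sp, 0.758)
  expect_identical(p1$mask, p2$mask)
  expect_identical(p1$intensity, p2$intensity)
  # seeds change the (orientation-dependent) geometry of branched shapes
  h4 <- renderCell(archetypeSpec("hypertrophic", seed = 4), 0.758)
  h5 <- renderCell(archetypeSpec("hypertrophic", seed = 5), 0.758)
  expect_false(identical(dim(h4$mask), dim(h5$mask)) &&
                 identical(h4$mask, h5$mask))
})

test_that("bipolar skeletons are unbranched; branch counts match an independent skeleton oracle", {
  for (sd in c(2, 5, 9)) {
    p <- renderCell(archetypeSpec("bipolar", seed = sd), 0.758)
    ss <- skeletonStats(p$mask, 0.758)
    expect_identical(ss$nBranchPoints, 0L)
    expect_equal(ss$longestBranchLength, ss$totalLength)
  }
  # branched archetypes: junction count agrees with an independent
  # thinning + junction-clustering oracle (different algorithms may
  # disagree by one junction on complex shapes)
  for (cl in c("hypertrophic", "inflamed_hypertrophic")) {
    p <- renderCell(archetypeSpec(cl, seed = 4), 0.758)
    ss <- skeletonStats(p$mask, 0.758)
    oj <- oracleJunctionCount(oracleThin(p$mask))
    expect_lte(abs(ss$nBranchPoints - oj), 1)
    expect_gte(ss$nBranchPoints,
               archetypeSpec(cl)$branchPoints)  # side branches present
  }
})

test_that("field rendering produces consistent ground truth", {
  specs <- lapply(1:5, function(k)
    list(spec = archetypeSpec(morphologyClasses()[k], seed = k),
         center = c(100 + 150 * ((k - 1) %/% 2), 100 + 180 * ((k - 1) %% 2))))
  fs <- fieldSpec(c(400, 460), cells = specs,
                  particles = list(
                    list(center = NULL, radius = 2.5, engulfedBy = 2),
                    list(center = c(30, 30), radius = 2.5, engulfedBy = NA)),
                  backgroundLevel = 10, noiseSd = 0)
  rf <- renderField(fs)
  expect_identical(sort(unique(as.vector(rf$labels))), 0:5)
  expect_equal(nrow(rf$cells), 5)
  # truth table covers every label exactly once; areas agree
  for (k in 1:5)
    expect_equal(sum(rf$labels == k), rf$cells$area_px[k])
  # engulfed particle strictly inside its host
  g <- greenChannel(rf$field)
  ppix <- which(g > 10 &
                  row(g) > rf$particles$center_row[1] - 6 &
                  row(g) < rf$particles$center_row[1] + 6 &
                  col(g) > rf$particles$center_col[1] - 6 &
                  col(g) < rf$particles$center_col[1] + 6)
  expect_true(all(rf$labels[ppix] == 2))
  # noise-free background is exactly the stated level
  bg <- redChannel(rf$field)[rf$labels == 0]
  expect_true(all(bg == 10))
  # determinism
  rf2 <- renderField(fs)
  expect_identical(redChannel(rf$field), redChannel(rf2$field))
  expect_identical(greenChannel(rf$field), greenChannel(rf2$field))
  # a cell positioned outside the image is rejected up front
  badSpecs <- specs
  badSpecs[[1]]$center <- c(600, 600)
  expect_error(fieldSpec(c(400, 460), cells = badSpecs), "outside")
})

test_that("time-lapse kinematics: co-movement, shrinkage, static free particles", {
  fs <- demoFieldSpec(n = 2, classes = c("round", "fried_egg"), seed = 3,
                      noiseSd = 0, nFreeParticles = 1, nEngulfed = 1,
                      particleRadius = 5)
  tl <- renderTimelapse(fs, nFrames = 3, motion = c(3, 0), shrinkRate = 0.2)
  pt <- lapply(tl$particles, function(p) p)
  # engulfed particle (id 1) centroid moves exactly with its host
  expect_equal(pt[[2]]$center_row[1] - pt[[1]]$center_row[1], 3)
  expect_equal(pt[[3]]$center_row[1] - pt[[2]]$center_row[1], 3)
  expect_equal(pt[[2]]$center_col[1] - pt[[1]]$center_col[1], 0)
  # area decays geometrically up to rasterization
  a <- vapply(pt, function(p) p$area_px[1], numeric(1))
  expect_lt(abs(a[2] / a[1] - 0.8), 0.06)
  expect_lt(abs(a[3] / a[2] - 0.8), 0.06)
  # free particle static
  expect_equal(pt[[3]]$center_row[2], pt[[1]]$center_row[2])
  expect_equal(pt[[3]]$center_col[2], pt[[1]]$center_col[2])
  expect_equal(pt[[3]]$area_px[2], pt[[1]]$area_px[2])
  # a displacement pushing the cell off the image is rejected
  expect_error(renderTimelapse(fs, nFrames = 60, motion = c(40, 0)),
               "frame")
})

test_that("field spec JSON and TIFF round-trips preserve the rendering", {
  fs <- demoFieldSpec(n = 2, classes = c("round", "bipolar"), seed = 6,
                      noiseSd = 1, nEngulfed = 1)
  js <- tempfile(fileext = ".json")
  writeFieldSpecJson(fs, js)
  fs2 <- readFieldSpecJson(js)
  r1 <- renderField(fs); r2 <- renderField(fs2)
  expect_identical(redChannel(r1$field), redChannel(r2$field))
  tf <- tempfile(fileext = ".tif")
  writeFieldTiff(r1$field, tf)
  back <- readFieldTiff(tf, pixelSize = pixelSize(r1$field))
  expect_lt(max(abs(redChannel(back[[1]]) - redChannel(r1$field))), 1e-4)
  mt <- tempfile(fileext = ".tif")
  writeLabelMaskTiff(r1$labels, mt)
  expect_identical(readLabelMaskTiff(mt), r1$labels)
})

test_that("the seven archetypes have pairwise-distinct derived-feature centroids", {
  cents <- t(vapply(morphologyClasses(), function(cl) {
    p <- renderCell(archetypeSpec(cl, seed = 21), 0.758)
    rec <- deriveFeatures(measureCells(p$mask, p$intensity, 0.758))
    unlist(rec[1, derivedFeatureNames()])
  }, numeric(10)))
  # scale each derived feature by its across-class spread, then require
  # clear pairwise separation (missing ratios compare as equal only if
  # both missing)
  sds <- apply(cents, 2, stats::sd, na.rm = TRUE)
  z <- sweep(cents, 2, ifelse(sds > 0, sds, 1), "/")
  for (i in 1:6) for (j in (i + 1):7) {
    d <- abs(z[i, ] - z[j, ])
    expect_gt(max(d, na.rm = TRUE), 0.3,
              label = paste("separation", rownames(z)[i], "vs", rownames(z)[j]))
  }
})
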