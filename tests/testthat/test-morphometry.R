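test_that("base features are exact on an axis-aligned rectangle", {
  m <- matrix(0L, 120, 70); m[11:110, 11:60] <- 1L
  rec <- measureCells(m, m * 1.0, pixelSize = 1)
  expect_equal(rec$Area, 5000)
  expect_equal(rec$ConvexArea, 5000)
  expect_equal(rec$LargestInscribedCircleRadius, 25)
  expect_equal(rec$Perimeter, 296)   # pixel-centre chain convention
  expect_equal(rec$CentroidRow_px, 60.5)
  expect_equal(rec$ImageBoundaryContact_Pixel, 0L)
  d <- deriveFeatures(rec)
  expect_equal(d$Solidity, 1)
})

test_that("geodesic diameter and perimeter agree with brute-force oracles on a disk", {
  disk <- makeDisk(30)
  rec <- measureCells(disk, disk * 1.0, pixelSize = 1)
  expect_lt(abs(rec$GeodesicDiameter - 60) / 60, 0.05)
  small <- makeDisk(7)
  recS <- measureCells(small, small * 1.0, pixelSize = 1)
  expect_equal(recS$GeodesicDiameter, oracleGeodesicDiameter(small),
               tolerance = 1e-9)
  # perimeter close to the circle length under the stated chain convention
  expect_lt(abs(rec$Perimeter - 2 * pi * 30) / (2 * pi * 30), 0.08)
})

test_that("derived features follow the printed formulas exactly", {
  rec <- data.frame(Area = 5000, ConvexArea = 6000, Perimeter = 300,
                    EllipsoidLongestAxisRadius = 40,
                    EllipsoidShortestAxisRadius = 20,
                    GeodesicDiameter = 90, LargestInscribedCircleRadius = 18,
                    RadiusAtBrightestPoint_Pixel = 12,
                    SkeletonTotalLength = 150,
                    SkeletonLongestBranchLength = 80,
                    SkeletonNumBranchPoints = 3L)
  d <- deriveFeatures(rec)
  expect_equal(d$Circularity, 5000 / 300^2)
  expect_equal(d$Solidity, 5000 / 6000)
  expect_equal(d$Roundness, 5000 / 1600)
  expect_equal(d$Roundness2, 5000 / 400)
  expect_equal(d$GeodesicElongation, 8100 / 5000)
  expect_equal(d$AspectRatio, 324 / 5000)
  expect_equal(d$Somaness, 144 / 5000)
  expect_equal(d$Branchiness, 3 / 90)
  expect_equal(d$Straightness, 6400 / 5000)
  expect_equal(d$Thickness, 5000 / 150^2)
  # unbranched straight cell: Branchiness 0; zero denominator -> NA
  rec$SkeletonNumBranchPoints <- 0L
  expect_equal(deriveFeatures(rec)$Branchiness, 0)
  rec$SkeletonTotalLength <- 0
  expect_true(is.na(deriveFeatures(rec)$Thickness))
})

test_that("boundary contact counts pixels on the image border once", {
  m <- matrix(0L, 50, 200)
  m[10:19, 50:59] <- 1L                        # interior
  expect_equal(unname(boundaryContact(m)["1"]), 0L)
  m2 <- matrix(0L, 50, 200)
  m2[1, 1:200] <- 1L; m2[2, 1:200] <- 1L       # full top edge, 2 px thick
  bc <- boundaryContact(m2)
  # 200 edge pixels counted once + the two row-2 pixels in the first and
  # last columns
  expect_equal(unname(bc["1"]), 202L)
  m3 <- matrix(0L, 50, 200)
  blob <- makeDisk(9)
  m3[seq_len(nrow(blob) - 3), 30 + seq_len(ncol(blob))] <-
    blob[4:nrow(blob), ]   # disk clipped by the top border
  bc3 <- boundaryContact(m3)
  border <- (row(m3) == 1 | row(m3) == nrow(m3) |
               col(m3) == 1 | col(m3) == ncol(m3))
  expect_equal(unname(bc3["1"]), sum(m3 == 1 & border))
})

test_that("the incompleteness filter uses a strict 1 percent rule", {
  rec <- data.frame(cell_id = 1:3, Perimeter = c(400, 400, 400),
                    PixelSize = 1,
                    ImageBoundaryContact_Pixel = c(0L, 4L, 5L))
  kept <- filterIncomplete(rec)
  expect_identical(kept$cell_id, c(1L, 2L))   # 4 is not above 4; 5 is
})

test_that("shape features are invariant under translation and quarter-turn rotation", {
  p <- renderCell(archetypeSpec("hypertrophic", seed = 6), 0.758)
  pad <- function(m, dr, dc, nr, nc) {
    out <- matrix(0, nr, nc)
    out[dr + seq_len(nrow(m)), dc + seq_len(ncol(m))] <- m
    out
  }
  nr <- nrow(p$mask) + 40; nc <- ncol(p$mask) + 40
  m0 <- pad(p$mask, 5, 5, nr, nc);   i0 <- pad(p$intensity, 5, 5, nr, nc)
  m1 <- pad(p$mask, 22, 31, nr, nc); i1 <- pad(p$intensity, 22, 31, nr, nc)
  rot90 <- function(m) t(m)[, rev(seq_len(nrow(m))), drop = FALSE]
  m2 <- rot90(m0); i2 <- rot90(i0)
  shape <- c(baseShapeFeatureNames(), derivedFeatureNames())
  r0 <- deriveFeatures(measureCells(m0, i0, 0.758))
  r1 <- deriveFeatures(measureCells(m1, i1, 0.758))
  r2 <- deriveFeatures(measureCells(m2, i2, 0.758))
  expect_equal(r1[, shape], r0[, shape], tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(r2[, shape], r0[, shape], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("pixel size scales lengths and areas but not the dimensionless ratios", {
  p <- renderCell(archetypeSpec("hypertrophic", seed = 8), 0.758)
  r1 <- deriveFeatures(measureCells(p$mask, p$intensity, 1))
  r2 <- deriveFeatures(measureCells(p$mask, p$intensity, 2))
  expect_equal(r2$Area, 4 * r1$Area)
  expect_equal(r2$Perimeter, 2 * r1$Perimeter)
  expect_equal(r2$GeodesicDiameter, 2 * r1$GeodesicDiameter)
  ratios <- setdiff(derivedFeatureNames(), "Branchiness")
  expect_equal(r2[, ratios], r1[, ratios], tolerance = 1e-12,
               ignore_attr = TRUE)
  # Branchiness is a count per unit length, so it scales inversely
  expect_equal(r2$Branchiness, r1$Branchiness / 2, tolerance = 1e-12)
})

test_that("degenerate labels are skipped with a warning", {
  m <- matrix(0L, 20, 20); m[5, 5] <- 1L; m[10:15, 10:15] <- 2L
  expect_warning(rec <- measureCells(m, m * 1.0, 1), "single pixel")
  expect_equal(rec$cell_id, 2)
})
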