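test_that("maximum projection is the per-pixel max over z", {
  a <- matrix(1:12, 3, 4)
  expect_identical(maxProject(list(a)), a)
  b <- matrix(12:1, 3, 4)
  set.seed(1)
  c3 <- matrix(runif(12, 0, 20), 3, 4)
  got <- maxProject(list(a, b, c3))
  brute <- a
  for (i in 1:3) for (j in 1:4) brute[i, j] <- max(a[i, j], b[i, j], c3[i, j])
  expect_equal(got, brute)
  expect_equal(maxProject(list(matrix(5, 1, 1), matrix(9, 1, 1),
                               matrix(3, 1, 1)))[1, 1], 9)
  expect_error(maxProject(list(a, matrix(0, 2, 2))), "mismatched")
})

test_that("Huang and IsoData thresholds match brute-force oracles on a two-spike histogram", {
  img <- matrix(c(rep(10, 1000), rep(100, 200)), 40, 30)
  h <- microgliaMorph:::.hist256(img)
  iso <- autoThreshold(img, "isodata")
  expect_equal(attr(iso, "threshold"), oracleIsodata(h$counts, h$mids),
               tolerance = 1e-9)
  expect_equal(attr(iso, "threshold"), 55, tolerance = 0.5)
  hu <- autoThreshold(img, "huang")
  expect_equal(attr(hu, "threshold"), oracleHuang(h$counts, h$mids),
               tolerance = 1e-9)
  # both fall between the modes and recover exactly the 200 bright pixels
  for (fg in list(iso, hu)) {
    thr <- attr(fg, "threshold")
    expect_true(thr > 10 && thr < 100)
    expect_equal(sum(fg), 200)
    expect_true(all(img[fg] == 100))
  }
  expect_error(autoThreshold(matrix(3, 5, 5)), "constant")
})

test_that("containment follows the strict majority rule", {
  cells <- matrix(0L, 40, 40)
  cells[5:24, 5:24] <- 3L
  p1 <- matrix(0, 40, 40); p1[10:12, 10:12] <- 1   # fully inside
  expect_equal(assignContainment(cells, p1)$host_cell_id, 3L)
  p2 <- matrix(0, 40, 40); p2[30:32, 30:32] <- 1   # on background
  expect_true(is.na(assignContainment(cells, p2)$host_cell_id))
  # straddling 60/40: 3 columns in, 2 out of a 5-wide particle
  p3 <- matrix(0, 40, 40); p3[10:11, 22:26] <- 1
  expect_equal(sum(cells[p3 > 0] == 3L), 6)
  expect_equal(assignContainment(cells, p3)$host_cell_id, 3L)
  # exactly 50/50: no host
  p4 <- matrix(0, 40, 40); p4[10:11, 23:26] <- 1
  expect_equal(sum(cells[p4 > 0] == 3L), 4)
  expect_true(is.na(assignContainment(cells, p4)$host_cell_id))
})

test_that("engulfment confirmation needs co-movement and shrinkage over >= 3 frames", {
  mk <- function(frames, rows, areas, host) {
    do.call(rbind, lapply(seq_along(frames), function(i)
      data.frame(particle_id = 1, frame_index = frames[i],
                 area_um2 = areas[i], area_px = areas[i],
                 centroid_row = rows[i], centroid_col = 0,
                 host_cell_id = host, track_id = 1)))
  }
  cellCent <- data.frame(frame_index = 1:4, cell_id = 7,
                         centroid_row = c(0, 3, 6, 9), centroid_col = 0)
  # co-moving and shrinking: confirmed, flagged for visual review
  good <- mk(1:4, c(0, 3, 6, 9), c(100, 90, 80, 70), 7L)
  cg <- confirmEngulfment(good, cellCent)
  expect_true(cg$confirmed)
  expect_true(cg$needs_review)
  # co-moving but constant area: fails the shrink criterion
  flat <- mk(1:4, c(0, 3, 6, 9), c(100, 100, 100, 100), 7L)
  expect_false(confirmEngulfment(flat, cellCent, minShrink = 0.1)$confirmed)
  # static particle near a moving cell: fails co-movement
  static <- mk(1:4, c(0, 0, 0, 0), c(100, 90, 80, 70), 7L)
  expect_false(confirmEngulfment(static, cellCent, coMoveTol = 2)$confirmed)
  # too few frames with a host
  short <- mk(1:2, c(0, 3), c(100, 80), 7L)
  cs <- confirmEngulfment(short, cellCent)
  expect_false(cs$confirmed)
  expect_true(cs$insufficient_data)
  # raising min_shrink never increases the confirmed count
  prev <- Inf
  for (ms in c(0.05, 0.2, 0.31, 0.5)) {
    n <- sum(confirmEngulfment(good, cellCent, minShrink = ms)$confirmed)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("phagocytosis statistics are plain arithmetic", {
  expect_equal(phagoIndex(50, 200, 5), 5)
  expect_equal(phagoIndex(0, 200, 5), 0)
  expect_equal(phagoIndex(200, 200, 1), 100)
  expect_warning(v <- phagoIndex(0, 0, 3), "undefined")
  expect_true(is.na(v))
  expect_equal(phagocytosingPct(c(rep(TRUE, 4), rep(FALSE, 21))), 16)
  expect_equal(phagocytosingPct(rep(FALSE, 10)), 0)
  expect_equal(phagocytosingPct(rep(TRUE, 3)), 100)
  expect_equal(deltaSytox(500, 300), 200)
  expect_equal(deltaSytox(300, 300), 0)
  expect_equal(deltaSytox(300, 500), -200)
})

test_that("full phagocytosis analysis matches the generator's ground truth", {
  fs <- demoFieldSpec(n = 4,
                      classes = c("round", "fried_egg", "hypertrophic",
                                  "bipolar"),
                      seed = 7, noiseSd = 0, nFreeParticles = 2,
                      nEngulfed = 2)
  tl <- renderTimelapse(fs, nFrames = 4, motion = c(3, 0), shrinkRate = 0.2)
  pa <- phagoAnalysis(tl$fields, tl$labels)
  px2 <- pixelSize(tl$fields[[1]])^2
  for (t in 1:4) {
    truth <- tl$particles[[t]]
    insideT <- sum(truth$area_px[!is.na(truth$engulfed_by)]) * px2
    totalT <- sum(truth$area_px) * px2
    rep_t <- pa$report[pa$report$frame_index == t, ]
    expect_equal(rep_t$sytox_area_inside, insideT, tolerance = 1e-9)
    expect_equal(rep_t$sytox_area_total, totalT, tolerance = 1e-9)
    expect_equal(rep_t$phago_index, (100 * insideT / totalT) / 4,
                 tolerance = 1e-9)
    # conservation: inside + outside = total, exactly
    pt <- pa$particles[pa$particles$frame_index == t, ]
    expect_equal(sum(pt$area_um2[!is.na(pt$host_cell_id)]) +
                   sum(pt$area_um2[is.na(pt$host_cell_id)]),
                 sum(pt$area_um2))
    expect_equal(sum(pt$area_um2), totalT, tolerance = 1e-9)
  }
  # exactly the engulfed particles are confirmed
  expect_equal(sum(pa$confirmations$confirmed), 2)
  expect_true(all(!is.na(pa$confirmations$host_cell_id[
    pa$confirmations$confirmed])))
  expect_equal(pa$report$phagocytosing_pct[1], 100 * 2 / 4)
  expect_equal(pa$deltaSytox,
               pa$report$sytox_area_total[4] - pa$report$sytox_area_total[1])
})
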