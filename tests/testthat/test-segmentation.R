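test_that("anisotropic diffusion conserves intensity and preserves strong edges", {
  # constant image is a fixed point
  u <- matrix(7, 20, 20)
  expect_equal(anisoDiffuse(u, 5, 5), u)
  # one step on a single bright pixel matches a hand-rolled update
  img <- matrix(0, 5, 5); img[3, 3] <- 100
  got <- anisoDiffuse(img, 1, conductance = 10)
  K <- 10; lam <- 0.2
  flux <- function(d) d * exp(-(d / K)^2)
  exp33 <- 100 + lam * 4 * flux(-100)          # centre loses to 4 axials
  exp23 <- 0 + lam * (flux(100) + 2 * flux(0) + flux(0))
  expect_equal(got[3, 3], exp33, tolerance = 1e-12)
  expect_equal(got[2, 3], exp23, tolerance = 1e-12)
  expect_equal(got[2, 2], 0)                   # diagonals see no flux
  # conservation under reflecting boundaries
  set.seed(4)
  r <- matrix(runif(900, 0, 50), 30, 30)
  sm <- anisoDiffuse(r, 15, 5)
  expect_lt(abs(sum(sm) - sum(r)) / sum(r), 1e-3)
  # a strong step edge stays put
  e <- matrix(10, 30, 30); e[, 16:30] <- 200
  sme <- anisoDiffuse(e, 10, 5)
  grad <- abs(diff(t(sme[15, , drop = FALSE])[, 1]))
  expect_equal(which.max(grad), 15)
  expect_error(anisoDiffuse(matrix(c(1, NA, 3, 4), 2)), "non-finite")
})

test_that("relative threshold is factor times the background mode", {
  img <- matrix(10, 50, 50); img[20:29, 20:29] <- 20
  fg <- relativeThreshold(img, 1.5)
  expect_equal(attr(fg, "threshold"), 15)
  expect_identical(unname(which(fg)), unname(which(img == 20)))
  fg2 <- relativeThreshold(img, 2.5)
  expect_equal(sum(fg2), 0)
  expect_warning(f <- relativeThreshold(matrix(5, 10, 10)), "flat")
  expect_equal(sum(f), 0)
  # on a noisy rendered field the foreground matches truth closely
  fs <- demoFieldSpec(n = 4, classes = c("round", "fried_egg"), seed = 8,
                      noiseSd = 1)
  rf <- renderField(fs)
  sm <- anisoDiffuse(redChannel(rf$field), 5, 5)
  fg3 <- relativeThreshold(sm, 1.5)
  truth <- rf$labels > 0
  jac <- sum(fg3 & truth) / sum(fg3 | truth)
  expect_gte(jac, 0.98)
})

test_that("labeling is 8-connected, raster-ordered, and filters by size and skeleton length", {
  px <- 1
  cfg <- segmentationConfig(minCellSize = 200, maxSkeletonLength = 450,
                            pixelSize = px)
  b <- matrix(FALSE, 100, 100)
  b[10:29, 10:29] <- TRUE    # 400 um2
  b[60:79, 60:79] <- TRUE    # 400 um2
  lab <- labelAndFilter(b, cfg)
  expect_identical(sort(unique(as.vector(lab))), c(0L, 1L, 2L))
  expect_true(all(lab[10:29, 10:29] == 1L))
  expect_true(all(lab[60:79, 60:79] == 2L))
  # diagonal contact joins components under 8-connectivity
  d <- matrix(FALSE, 60, 60)
  d[10:24, 10:24] <- TRUE
  d[25:39, 25:39] <- TRUE
  expect_equal(max(labelAndFilter(d, cfg)), 1)
  # 150 um2 blob is below the published minimum cell size and is removed
  s <- matrix(FALSE, 40, 40); s[10:24, 10:19] <- TRUE  # 150 px = 150 um2
  expect_equal(max(labelAndFilter(s, cfg)), 0)
  # a long snake exceeds the skeleton-length maximum and is removed
  sn <- snakeMask(c(120, 120), margin = 10, rowStep = 12, nPx = 600)
  ss <- skeletonStats(sn, px)
  expect_gt(ss$totalLength, 450)
  expect_gt(sum(sn) * px^2, 200)
  expect_equal(max(labelAndFilter(sn, cfg)), 0)
  expect_equal(max(labelAndFilter(
    sn, segmentationConfig(maxSkeletonLength = 1e5, pixelSize = px))), 1)
  # raising the size floor never increases the label count
  mix <- matrix(FALSE, 120, 120)
  mix[5:34, 5:34] <- TRUE; mix[50:67, 50:67] <- TRUE; mix[90:99, 90:99] <- TRUE
  prev <- Inf
  for (minSize in c(50, 150, 400, 1000)) {
    k <- max(labelAndFilter(mix, segmentationConfig(minCellSize = minSize,
                                                    pixelSize = px)))
    expect_lte(k, prev)
    prev <- k
  }
})

test_that("scripted mask edits split and merge labels", {
  m <- matrix(0L, 40, 40)
  m[5:14, 5:34] <- 1L
  m[25:34, 5:14] <- 2L
  m[25:34, 25:34] <- 3L
  merged <- applyEdits(m, list(maskEditMerge(c(2, 3))))
  expect_equal(length(setdiff(unique(as.vector(merged)), 0L)), 2)
  expect_equal(unique(merged[m %in% c(2, 3)]), 2L)
  split <- applyEdits(m, list(maskEditSplit(1, cbind(c(2, 20), c(20, 20)))))
  labs <- setdiff(unique(as.vector(split)), 0L)
  expect_equal(length(labs), 4)     # labels 2, 3 untouched + two pieces
  expect_true(all(split[m %in% c(2, 3)] == m[m %in% c(2, 3)]))
  # split then merge restores the partition up to the removed polyline
  back <- applyEdits(split, list(maskEditMerge(setdiff(labs, c(2, 3)))))
  expect_true(all((back > 0) == (m > 0 & split != 0 |
                                   m %in% c(2, 3))[seq_along(m)] |
                    (m == 1 & back == 0)))
  restored <- back > 0
  original <- m > 0
  removed <- original & !restored
  expect_true(all(m[removed] == 1))      # only polyline pixels missing
  expect_lt(sum(removed), 45)
  # a polyline that misses the label is a warned no-op
  expect_warning(same <- applyEdits(m, list(
    maskEditSplit(2, cbind(c(1, 1), c(1, 40))))), "no-op")
  expect_identical(same, m)
  expect_error(applyEdits(m, list(maskEditMerge(c(2, 9)))), "missing")
})

test_that("tracking propagates identities by maximal overlap", {
  base <- matrix(0L, 60, 60)
  base[10:19, 10:19] <- 1L
  base[40:49, 40:49] <- 2L
  # static field: ids constant
  tr <- trackMasks(list(base, base, base))
  expect_identical(tr[[3]], base)
  # translation well above the overlap gate keeps the id
  mv <- lapply(0:2, function(t) {
    m <- matrix(0L, 60, 60)
    m[10:19 + 3 * t, 10:19] <- 1L
    m[40:49, 40:49] <- 2L
    m
  })
  trm <- trackMasks(mv)
  expect_equal(unique(as.vector(trm[[3]][16:25, 10:19])), 1L)
  # disappearance then a new cell elsewhere: fresh, unused id
  f3 <- matrix(0L, 60, 60)
  f3[40:49, 40:49] <- 1L    # old cell 2 persists (different input label)
  f3[2:9, 50:57] <- 2L      # newcomer
  tr2 <- trackMasks(list(base, f3))
  expect_equal(unique(as.vector(tr2[[2]][40:49, 40:49])), 2L)  # inherited
  newcomer <- unique(as.vector(tr2[[2]][2:9, 50:57]))
  expect_false(newcomer %in% c(1L, 2L))
})

test_that("a rendered time-lapse tracks cells through motion", {
  fs <- demoFieldSpec(n = 2, classes = c("round", "fried_egg"), seed = 12,
                      noiseSd = 0)
  tl <- renderTimelapse(fs, nFrames = 3, motion = c(3, 0))
  cfg <- segmentationConfig(diffusionIterations = 3)
  masks <- trackMasks(lapply(tl$fields, segmentFrame, config = cfg))
  for (t in 1:3) {
    j <- truthJaccard(masks[[t]], tl$labels[[t]])
    expect_true(all(j > 0.95))
  }
  # identity of each truth cell is stable over frames
  for (k in 1:2) {
    ids <- vapply(1:3, function(t) {
      ov <- table(masks[[t]][tl$labels[[t]] == k])
      as.integer(names(ov)[which.max(ov)])
    }, integer(1))
    expect_equal(length(unique(ids)), 1)
  }
})
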