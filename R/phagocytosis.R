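# Phagocytosis quantification from two-channel time-lapses: maximum
# projection, histogram auto-thresholding (Huang fuzzy entropy / IsoData
# intermeans), inside/outside particle bookkeeping against the cell label
# mask, engulfment confirmation across frames (co-movement + shrinkage;
# the phagosome-pouch criterion is visual and is surfaced as a
# needs_review flag, never automated), and the summary statistics:
# phagocytosis index, phagocytosing-cell percentage and the debris-area
# change between two named frames.

#' Maximum intensity projection
#'
#' @param zstack list of equally sized matrices, or a 3-d array with the
#'   z planes in the third dimension.
#' @return matrix of per-pixel maxima.
#' @export
maxProject <- function(zstack) {
  if (is.array(zstack) && length(dim(zstack)) == 3)
    zstack <- lapply(seq_len(dim(zstack)[3]), function(i) zstack[, , i])
  stopifnot(length(zstack) >= 1)
  d <- dim(zstack[[1]])
  for (p in zstack)
    if (!all(dim(p) == d)) stop("z planes have mismatched dimensions")
  Reduce(pmax, zstack)
}

# 256-bin histogram shared by the auto-threshold methods
.hist256 <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) stop("constant image: cannot auto-threshold")
  brk <- seq(rng[1], rng[2], length.out = 257)
  bin <- findInterval(image, brk, all.inside = TRUE)
  list(counts = tabulate(bin, 256), mids = (brk[-1] + brk[-257]) / 2,
       breaks = brk)
}

# IsoData / intermeans: iterate t <- (mean below + mean above) / 2 on the
# binned histogram until the fixed point
.isodataBin <- function(counts, mids) {
  t <- sum(counts * mids) / sum(counts)
  repeat {
    lo <- mids <= t
    mLo <- if (any(counts[lo] > 0)) sum(counts[lo] * mids[lo]) / sum(counts[lo]) else min(mids)
    mHi <- if (any(counts[!lo] > 0)) sum(counts[!lo] * mids[!lo]) / sum(counts[!lo]) else max(mids)
    tNew <- (mLo + mHi) / 2
    if (abs(tNew - t) < .Machine$double.eps^0.5 * max(1, abs(t))) break
    t <- tNew
  }
  t
}

# Huang: choose the bin threshold minimizing the fuzzy Shannon entropy of
# the membership function mu(g) = 1 / (1 + |g - m(class of g)| / C)
.huangBin <- function(counts, mids) {
  C <- diff(range(mids))
  n <- length(mids)
  best <- Inf; bestT <- mids[1]
  cw <- cumsum(counts)
  cwm <- cumsum(counts * mids)
  total <- cw[n]; totalM <- cwm[n]
  for (k in seq_len(n - 1)) {
    w0 <- cw[k]; w1 <- total - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- cwm[k] / w0
    mu1 <- (totalM - cwm[k]) / w1
    m <- ifelse(seq_len(n) <= k, mu0, mu1)
    u <- 1 / (1 + abs(mids - m) / C)
    h <- -(u * log(u) + (1 - u) * log(pmax(1 - u, .Machine$double.xmin)))
    h[u >= 1] <- 0
    S <- sum(counts * h)
    if (S < best) { best <- S; bestT <- (mids[k] + mids[k + 1]) / 2 }
  }
  bestT
}

#' Histogram auto-thresholding
#'
#' Computes a global threshold from the 256-bin histogram of the image
#' using either Huang's fuzzy-entropy minimization or the IsoData
#' (iterative intermeans) algorithm; foreground is every pixel strictly
#' above the threshold. Huang tends to be the appropriate choice for the
#' diffuse reporter channel and IsoData for the punctate particle
#' channel.
#'
#' @param image numeric matrix with at least two distinct grey levels.
#' @param method "huang" or "isodata".
#' @return logical foreground matrix with the threshold attached as
#'   attribute `"threshold"`.
#' @export
autoThreshold <- function(image, method = c("huang", "isodata")) {
  method <- match.arg(method)
  h <- .hist256(image)
  thr <- switch(method,
                huang = .huangBin(h$counts, h$mids),
                isodata = .isodataBin(h$counts, h$mids))
  out <- image > thr
  attr(out, "threshold") <- thr
  out
}

#' Particle containment for one frame
#'
#' Labels the particle foreground (8-connected) and assigns each particle
#' to the cell overlapping more than half of its area; a particle with no
#' strict-majority host (including an exact 50/50 straddle) is outside.
#'
#' @param cellMask integer cell label mask.
#' @param particleMask logical/0-1 particle foreground, or an integer
#'   particle label mask.
#' @param pixelSize micrometres per pixel (areas in um^2; 1 = pixels).
#' @param frame frame index stored in the records.
#' @return data.frame: particle_id, frame_index, area_um2, area_px,
#'   centroid_row, centroid_col, host_cell_id (NA = outside).
#' @export
assignContainment <- function(cellMask, particleMask, pixelSize = 1,
                              frame = 1L) {
  stopifnot(all(dim(cellMask) == dim(particleMask)))
  plab <- if (.isBinary(particleMask)) .label8(particleMask)
          else matrix(as.integer(particleMask), nrow(particleMask))
  rows <- list()
  for (j in seq_len(max(plab, 0L))) {
    idx <- which(plab == j)
    if (!length(idx)) next
    n <- length(idx)
    r <- (idx - 1L) %% nrow(plab) + 1L
    c <- (idx - 1L) %/% nrow(plab) + 1L
    host <- NA_integer_
    ov <- table(cellMask[idx][cellMask[idx] > 0])
    if (length(ov)) {
      top <- which.max(ov)
      if (ov[[top]] > n / 2) host <- as.integer(names(ov)[top])
    }
    rows[[length(rows) + 1L]] <- data.frame(
      particle_id = j, frame_index = frame,
      area_um2 = n * pixelSize^2, area_px = n,
      centroid_row = mean(r), centroid_col = mean(c),
      host_cell_id = host)
  }
  if (!length(rows))
    return(data.frame(particle_id = integer(), frame_index = integer(),
                      area_um2 = numeric(), area_px = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      host_cell_id = integer()))
  do.call(rbind, rows)
}

#' Link particles across frames
#'
#' Nearest-centroid linking: a particle at frame t inherits the track of
#' the frame t-1 particle whose centroid is nearest, provided the step is
#' at most `maxStep` (default: the particle's equivalent diameter).
#' Unmatched particles start new tracks.
#'
#' @param frames list of per-frame particle tables from
#'   [assignContainment()].
#' @param maxStep maximum centroid step in pixels (default data-driven).
#' @return one data.frame with a `track_id` column.
#' @export
trackParticles <- function(frames, maxStep = NULL) {
  stopifnot(length(frames) >= 1)
  prev <- frames[[1]]
  prev$track_id <- seq_len(nrow(prev))
  nextId <- nrow(prev)
  out <- list(prev)
  for (t in seq_along(frames)[-1]) {
    cur <- frames[[t]]
    cur$track_id <- NA_integer_
    if (nrow(cur) && nrow(prev)) {
      usedPrev <- logical(nrow(prev))
      ord <- order(-cur$area_px)
      for (i in ord) {
        dx <- prev$centroid_row - cur$centroid_row[i]
        dy <- prev$centroid_col - cur$centroid_col[i]
        dd <- sqrt(dx^2 + dy^2)
        lim <- if (is.null(maxStep)) 2 * sqrt(cur$area_px[i] / pi) + 2
               else maxStep
        dd[usedPrev] <- Inf
        jm <- which.min(dd)
        if (length(jm) && dd[jm] <= lim) {
          cur$track_id[i] <- prev$track_id[jm]
          usedPrev[jm] <- TRUE
        }
      }
    }
    fresh <- is.na(cur$track_id)
    if (any(fresh)) {
      cur$track_id[fresh] <- nextId + seq_len(sum(fresh))
      nextId <- nextId + sum(fresh)
    }
    out[[t]] <- cur
    prev <- cur
  }
  do.call(rbind, out)
}

#' Confirm engulfment of tracked particles
#'
#' A tracked particle is a confirmed engulfment iff (a) it has a host
#' cell and moves with it: the per-frame difference between the particle
#' displacement and its host-cell displacement stays within `coMoveTol`
#' pixels, and (b) its area decreases by at least `minShrink` (fraction)
#' over the observation window. The third published criterion, visible
#' phagosome pouches, cannot be automated; confirmed records therefore
#' carry `needs_review = TRUE`. Particles tracked (with a host) for fewer
#' than 3 frames are never confirmed and are flagged
#' `insufficient_data`.
#'
#' @param particleTracks data.frame from [trackParticles()].
#' @param cellCentroids data.frame with columns frame_index, cell_id,
#'   centroid_row, centroid_col (host-cell positions per frame).
#' @param minShrink minimum fractional area decrease (default 0.1).
#' @param coMoveTol per-frame co-movement tolerance in pixels (default 2).
#' @return per-track data.frame: track_id, host_cell_id, n_frames,
#'   co_movement_score (max per-frame deviation), shrinkage (fractional),
#'   confirmed, needs_review, insufficient_data.
#' @export
confirmEngulfment <- function(particleTracks, cellCentroids,
                              minShrink = 0.1, coMoveTol = 2) {
  out <- list()
  for (id in unique(particleTracks$track_id)) {
    tr <- particleTracks[particleTracks$track_id == id, , drop = FALSE]
    tr <- tr[order(tr$frame_index), , drop = FALSE]
    hosts <- unique(tr$host_cell_id[!is.na(tr$host_cell_id)])
    host <- if (length(hosts) == 1) hosts else NA_integer_
    nWithHost <- sum(!is.na(tr$host_cell_id))
    if (is.na(host) || nWithHost < 3) {
      out[[length(out) + 1L]] <- data.frame(
        track_id = id, host_cell_id = host, n_frames = nrow(tr),
        co_movement_score = NA_real_, shrinkage = NA_real_,
        confirmed = FALSE, needs_review = FALSE,
        # insufficient only when a hosted particle lacks frames; a free
        # particle with a full track is simply not an engulfment
        insufficient_data = !is.na(host) || (nrow(tr) < 3))
      next
    }
    hc <- cellCentroids[cellCentroids$cell_id == host, , drop = FALSE]
    hc <- hc[match(tr$frame_index, hc$frame_index), , drop = FALSE]
    dpr <- diff(tr$centroid_row); dpc <- diff(tr$centroid_col)
    dhr <- diff(hc$centroid_row); dhc <- diff(hc$centroid_col)
    dev <- sqrt((dpr - dhr)^2 + (dpc - dhc)^2)
    coMove <- max(dev)
    shrink <- (tr$area_px[1] - tr$area_px[nrow(tr)]) / tr$area_px[1]
    confirmed <- isTRUE(coMove <= coMoveTol) && isTRUE(shrink >= minShrink)
    out[[length(out) + 1L]] <- data.frame(
      track_id = id, host_cell_id = host, n_frames = nrow(tr),
      co_movement_score = coMove, shrinkage = shrink,
      confirmed = confirmed, needs_review = confirmed,
      insufficient_data = FALSE)
  }
  do.call(rbind, out)
}

#' Phagocytosis index
#'
#' `[100 x (debris area inside microglia / total debris area)] / number of
#' microglia in the field`: the engulfed fraction of the stained debris,
#' normalized to the number of microglia per field.
#'
#' @param insideArea debris area inside cells (um^2).
#' @param totalArea total debris area (um^2, > 0).
#' @param nMicroglia number of microglia in the field (>= 1).
#' @return the index (NA with a warning if there is no debris).
#' @export
phagoIndex <- function(insideArea, totalArea, nMicroglia) {
  stopifnot(nMicroglia >= 1, insideArea >= 0)
  if (totalArea <= 0) {
    warning("total debris area is zero: index undefined")
    return(NA_real_)
  }
  (100 * insideArea / totalArea) / nMicroglia
}

#' Percentage of phagocytosing microglia
#'
#' 100 x (cells with at least one confirmed engulfed particle) / (total
#' cells).
#'
#' @param confirmedByCell logical vector, one entry per microglia.
#' @return percentage in [0, 100].
#' @export
phagocytosingPct <- function(confirmedByCell) {
  stopifnot(length(confirmedByCell) >= 1)
  100 * mean(confirmedByCell)
}

#' Debris-area change between two frames
#'
#' `areaLate - areaEarly`, reported as-is (negative values are meaningful:
#' debris cleared faster than it was produced). Both areas must come from
#' identical thresholding settings.
#'
#' @param areaLate,areaEarly total debris areas (um^2).
#' @return signed difference.
#' @export
deltaSytox <- function(areaLate, areaEarly) areaLate - areaEarly

#' Phagocytosis analysis of a two-channel time-lapse
#'
#' Per frame: thresholds the particle channel, books particles against
#' the provided cell masks, then links particles over time and confirms
#' engulfments; returns per-frame reports and the per-track confirmation
#' table.
#'
#' @param fields list of [Field-class] frames.
#' @param cellMasks list of tracked integer cell label masks (same
#'   length).
#' @param particleMethod threshold method for the green channel:
#'   "isodata" or "huang" (see [autoThreshold()]) or "relative"
#'   ([relativeThreshold()] at `particleFactor` times the background
#'   mode). The histogram methods suit fields with substantial debris;
#'   when debris covers only a vanishing pixel fraction their threshold
#'   collapses into the background noise, and the relative threshold is
#'   the robust choice.
#' @param particleFactor factor for the relative method (default 1.5).
#' @param minParticleSize minimum particle area in um^2 (default 2):
#'   thresholding a noisy field always yields a sprinkle of single-pixel
#'   speckles, which are not debris; the floor removes them, the exact
#'   analogue of the minimum cell size on the reporter channel.
#' @param minShrink,coMoveTol see [confirmEngulfment()].
#' @param deltaFrames c(early, late) frame indices for the debris-area
#'   change (default first and last frame).
#' @return list: `report` (per-frame data.frame with sytox_area_inside,
#'   sytox_area_total, n_microglia, phago_index, n_phagocytosing,
#'   phagocytosing_pct), `particles` (tracked particle records),
#'   `confirmations`, `deltaSytox`.
#' @export
phagoAnalysis <- function(fields, cellMasks,
                          particleMethod = c("isodata", "huang", "relative"),
                          particleFactor = 1.5,
                          minParticleSize = 2,
                          minShrink = 0.1, coMoveTol = 2,
                          deltaFrames = NULL) {
  particleMethod <- match.arg(particleMethod)
  stopifnot(length(fields) == length(cellMasks), length(fields) >= 1)
  nF <- length(fields)
  perFrame <- vector("list", nF)
  cellCent <- list()
  for (t in seq_len(nF)) {
    f <- fields[[t]]
    px <- pixelSize(f)
    pm <- if (particleMethod == "relative")
      relativeThreshold(greenChannel(f), particleFactor)
    else autoThreshold(greenChannel(f), particleMethod)
    plab <- .label8(pm)
    if (minParticleSize > 0 && max(plab) > 0) {
      sizes <- tabulate(plab[plab > 0])
      drop <- which(sizes * px^2 < minParticleSize)
      plab[plab %in% drop] <- 0L
      plab <- .compactLabels(plab)
    }
    perFrame[[t]] <- assignContainment(cellMasks[[t]], plab,
                                       pixelSize = px, frame = t)
    labs <- setdiff(sort(unique(as.vector(cellMasks[[t]]))), 0L)
    for (l in labs) {
      idx <- which(cellMasks[[t]] == l)
      cellCent[[length(cellCent) + 1L]] <- data.frame(
        frame_index = t, cell_id = l,
        centroid_row = mean((idx - 1) %% nrow(cellMasks[[t]]) + 1),
        centroid_col = mean((idx - 1) %/% nrow(cellMasks[[t]]) + 1))
    }
  }
  cellCent <- do.call(rbind, cellCent)
  tracks <- trackParticles(perFrame)
  conf <- confirmEngulfment(tracks, cellCent,
                            minShrink = minShrink, coMoveTol = coMoveTol)
  confirmedHosts <- unique(conf$host_cell_id[conf$confirmed])
  report <- do.call(rbind, lapply(seq_len(nF), function(t) {
    pt <- perFrame[[t]]
    labs <- setdiff(sort(unique(as.vector(cellMasks[[t]]))), 0L)
    inside <- sum(pt$area_um2[!is.na(pt$host_cell_id)])
    total <- sum(pt$area_um2)
    nCells <- length(labs)
    data.frame(frame_index = t,
               sytox_area_inside = inside, sytox_area_total = total,
               n_microglia = nCells,
               phago_index = if (nCells >= 1 && total > 0)
                 phagoIndex(inside, total, nCells) else NA_real_,
               n_phagocytosing = sum(labs %in% confirmedHosts),
               phagocytosing_pct = if (nCells >= 1)
                 100 * sum(labs %in% confirmedHosts) / nCells else NA_real_)
  }))
  if (is.null(deltaFrames)) deltaFrames <- c(1L, nF)
  dS <- deltaSytox(report$sytox_area_total[deltaFrames[2]],
                   report$sytox_area_total[deltaFrames[1]])
  list(report = report, particles = tracks, confirmations = conf,
       deltaSytox = dS)
}
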