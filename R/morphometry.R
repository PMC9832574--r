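# Per-cell morphometric and intensity features from a label mask plus the
# intensity frame it was derived from, the ten derived shape ratios, and
# the image-boundary incompleteness filter.
#
# Conventions (stated because every tool differs): the perimeter is the
# length of the 8-connected pixel-center boundary chain (axial step 1,
# diagonal step sqrt(2), summed over all components of the label); the
# convex area is the area of the convex hull of the pixel squares (so
# Area <= ConvexArea always); ellipse radii are moment-based semi-axes of
# the best-fit uniform ellipse (with the 1/12 single-pixel variance term);
# the geodesic diameter is the exact longest within-mask shortest path
# between boundary pixels (quasi-Euclidean 1/sqrt(2) steps); skeleton
# features follow skeletonStats(), computed in a canonical quarter-turn
# orientation so they are exactly invariant under 90-degree rotation.

# Moore boundary tracing of the 8-connected component containing `startPx`
# (index into mask); returns the closed chain of pixel indices
.traceContour <- function(mask, startPx) {
  dims <- dim(mask)
  # clockwise Moore neighbourhood starting north (row - 1)
  offs <- cbind(dr = c(-1, -1, 0, 1, 1, 1, 0, -1),
                dc = c(0, 1, 1, 1, 0, -1, -1, -1))
  r0 <- (startPx - 1L) %% dims[1] + 1L
  c0 <- (startPx - 1L) %/% dims[1] + 1L
  isFg <- function(r, c) r >= 1 && r <= dims[1] && c >= 1 && c <= dims[2] &&
    mask[r, c] > 0
  chain <- list(c(r0, c0))
  # entered the start pixel "from the west" (raster scan)
  dirFrom <- 7L  # index of west in offs
  r <- r0; c <- c0
  firstStep <- NULL
  maxIter <- 8L * sum(mask > 0) + 8L
  for (it in seq_len(maxIter)) {
    found <- FALSE
    for (k in seq_len(8L)) {
      j <- ((dirFrom - 1L + k) %% 8L) + 1L
      rn <- r + offs[j, 1]; cn <- c + offs[j, 2]
      if (isFg(rn, cn)) {
        step <- c(r, c, rn, cn)
        if (!is.null(firstStep) && all(step == firstStep))
          return(do.call(rbind, chain[-length(chain)]))
        if (is.null(firstStep)) firstStep <- step
        chain[[length(chain) + 1L]] <- c(rn, cn)
        # next scan starts one past the direction we came from
        dirFrom <- ((j - 1L + 4L) %% 8L) + 1L
        r <- rn; c <- cn
        found <- TRUE
        break
      }
    }
    if (!found) return(matrix(c(r0, c0), 1))  # isolated pixel
  }
  do.call(rbind, chain)
}

# perimeter (pixel units) of one label: sum of boundary-chain step lengths
# over its 8-connected components
.perimeterPx <- function(mask) {
  lab <- .label8(mask)
  total <- 0
  for (k in seq_len(max(lab))) {
    comp <- lab == k
    n <- sum(comp)
    if (n == 1) { total <- total + 2; next }  # degenerate: out-and-back
    start <- which(comp)[which.min(.rasterRank(which(comp), dim(comp)))]
    ch <- .traceContour(comp, start)
    if (nrow(ch) < 2) { total <- total + 2; next }
    ch2 <- rbind(ch, ch[1, ])
    d <- abs(diff(ch2[, 1])) + abs(diff(ch2[, 2]))
    total <- total + sum(ifelse(d == 2, sqrt(2), d))
  }
  total
}

# convex hull area (pixel^2) from the corners of the boundary pixels
.convexAreaPx <- function(mask) {
  idx <- which(mask > 0)
  dims <- dim(mask)
  r <- (idx - 1L) %% dims[1] + 1L
  c <- (idx - 1L) %/% dims[1] + 1L
  if (length(idx) > 4) {
    # hull vertices come from pixels with a background 4-neighbour
    bnd <- .boundaryPixels(mask)
    r <- bnd$row; c <- bnd$col
  }
  x <- c(c - 0.5, c + 0.5, c - 0.5, c + 0.5)
  y <- c(r - 0.5, r - 0.5, r + 0.5, r + 0.5)
  h <- grDevices::chull(x, y)
  .polygonArea(x[h], y[h])
}

# pixels of a mask with a background 4-neighbour (or on the matrix edge)
.boundaryPixels <- function(mask) {
  dims <- dim(mask)
  idx <- which(mask > 0)
  r <- (idx - 1L) %% dims[1] + 1L
  c <- (idx - 1L) %/% dims[1] + 1L
  bg <- function(rr, cc) {
    out <- rr < 1 | rr > dims[1] | cc < 1 | cc > dims[2]
    inb <- !out
    out[inb] <- mask[cbind(rr[inb], cc[inb])] == 0
    out
  }
  isB <- bg(r - 1, c) | bg(r + 1, c) | bg(r, c - 1) | bg(r, c + 1)
  list(idx = idx[isB], row = r[isB], col = c[isB])
}

# geodesic diameter (pixel units) of a mask: max over boundary-pixel
# pairs of the within-mask shortest path. The path metric uses axial,
# diagonal and knight steps (1, sqrt(2), sqrt(5)); knight steps require
# both intermediate pixels inside the mask so paths cannot tunnel through
# background. The 3-step neighbourhood keeps the chamfer error against
# true Euclidean path length below ~2%. Disconnected labels: max over
# components.
.geodesicDiameterPx <- function(mask) {
  idx <- which(mask > 0)
  n <- length(idx)
  if (n <= 1) return(0)
  dims <- dim(mask)
  id <- matrix(0L, dims[1], dims[2]); id[idx] <- seq_len(n)
  r <- (idx - 1L) %% dims[1] + 1L
  c <- (idx - 1L) %/% dims[1] + 1L
  el <- list(); wl <- list()
  inM <- function(rr, cc) {
    ok <- rr >= 1 & rr <= dims[1] & cc >= 1 & cc <= dims[2]
    ok[ok] <- mask[cbind(rr[ok], cc[ok])] > 0
    ok
  }
  steps <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)),
                c(1, 2, sqrt(5)), c(2, 1, sqrt(5)),
                c(-1, 2, sqrt(5)), c(-2, 1, sqrt(5)))
  for (s in steps) {
    r2 <- r + s[1]; c2 <- c + s[2]
    ok <- inM(r2, c2)
    if (s[3] > 2) {
      # knight step: both stepping stones must be inside the mask
      ok <- ok & inM(r + round(s[1] / 2), c + round(s[2] / 2)) &
                 inM(r + s[1] - round(s[1] / 2), c + s[2] - round(s[2] / 2))
    }
    if (any(ok)) {
      el[[length(el) + 1L]] <- cbind(id[cbind(r[ok], c[ok])],
                                     id[cbind(r2[ok], c2[ok])])
      wl[[length(wl) + 1L]] <- rep(s[3], sum(ok))
    }
  }
  if (!length(el)) return(0)
  g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
  igraph::E(g)$weight <- unlist(wl)
  src <- id[.boundaryPixels(mask)$idx]
  d <- igraph::distances(g, v = src, to = src, algorithm = "dijkstra")
  max(d[is.finite(d)])
}

#' Per-cell image-boundary contact counts
#'
#' Counts, for every label, the number of its pixels lying on the first or
#' last row or column of the image (corner pixels count once).
#'
#' @param mask integer label mask.
#' @return named integer vector (names = label ids).
#' @export
boundaryContact <- function(mask) {
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  border <- matrix(FALSE, nrow(mask), ncol(mask))
  border[c(1, nrow(mask)), ] <- TRUE
  border[, c(1, ncol(mask))] <- TRUE
  out <- vapply(labs, function(l) sum(mask == l & border), integer(1))
  stats::setNames(out, labs)
}

#' Measure base morphometric features
#'
#' Computes, for every label in the mask, the base shape and intensity
#' features: area, convex area, perimeter, moment-ellipse axis radii,
#' geodesic diameter, largest-inscribed-circle radius, the inscribed
#' radius at the brightest pixel, skeleton total/longest-branch length and
#' branch-point count, intensity summaries, centroid and image-boundary
#' contact. Lengths are in micrometres and areas in square micrometres
#' (centroids and the boundary-contact count are in pixels).
#'
#' @param mask integer label mask.
#' @param image intensity matrix the mask was derived from.
#' @param pixelSize micrometres per pixel.
#' @param frame frame index stored in the records.
#' @param brightest "raw" (default) or "smoothed": intensity image used to
#'   locate the brightest pixel (smoothed = 3x3 mean).
#' @return data.frame with one row per label (a cell record table).
#' @export
measureCells <- function(mask, image, pixelSize, frame = 1L,
                         brightest = c("raw", "smoothed")) {
  stopifnot(all(dim(mask) == dim(image)), pixelSize > 0)
  brightest <- match.arg(brightest)
  bImg <- image
  if (brightest == "smoothed") {
    acc <- matrix(0, nrow(image), ncol(image))
    for (dr in -1:1) for (dc in -1:1)
      acc <- acc + .shiftMat(image, dr, dc, fill = 0)
    bImg <- acc / 9
  }
  labs <- setdiff(sort(unique(as.vector(mask))), 0L)
  contact <- boundaryContact(mask)
  rows <- list()
  for (l in labs) {
    idx <- which(mask == l)
    if (length(idx) < 1) next
    if (length(idx) == 1) {
      warning("label ", l, " has a single pixel; skipped")
      next
    }
    dims <- dim(mask)
    pr <- (idx - 1L) %% dims[1] + 1L
    pc <- (idx - 1L) %/% dims[1] + 1L
    cr <- .cropMask(mask == l)
    m <- cr$mask
    n <- length(idx)
    areaUm2 <- n * pixelSize^2
    convexUm2 <- .convexAreaPx(m) * pixelSize^2
    perimUm <- .perimeterPx(m) * pixelSize
    # moment ellipse (population moments + 1/12 pixel term)
    mr <- mean(pr); mc <- mean(pc)
    vrr <- mean((pr - mr)^2) + 1 / 12
    vcc <- mean((pc - mc)^2) + 1 / 12
    vrc <- mean((pr - mr) * (pc - mc))
    ev <- eigen(matrix(c(vrr, vrc, vrc, vcc), 2), symmetric = TRUE)$values
    ev <- pmax(ev, 0)
    longAxis <- 2 * sqrt(ev[1]) * pixelSize
    shortAxis <- 2 * sqrt(ev[2]) * pixelSize
    geo <- .geodesicDiameterPx(m) * pixelSize
    dm <- matrix(EBImage::distmap(m), nrow(m), ncol(m))
    licr <- max(dm) * pixelSize
    # brightest pixel of the cell; ties resolved by the (rotation-
    # invariant) largest inscribed radius among the tied pixels
    bvals <- bImg[idx]
    tied <- which(bvals == max(bvals))
    dmFull <- dm[cbind(pr[tied] - cr$rowOffset, pc[tied] - cr$colOffset)]
    rabp <- max(dmFull) * pixelSize
    ss <- skeletonStats(.canonicalRotation(m), pixelSize)
    iv <- image[idx]
    rows[[length(rows) + 1L]] <- data.frame(
      cell_id = l, frame_index = frame,
      Area = areaUm2, ConvexArea = convexUm2, Perimeter = perimUm,
      EllipsoidLongestAxisRadius = longAxis,
      EllipsoidShortestAxisRadius = shortAxis,
      GeodesicDiameter = geo, LargestInscribedCircleRadius = licr,
      RadiusAtBrightestPoint_Pixel = rabp,
      SkeletonTotalLength = ss$totalLength,
      SkeletonLongestBranchLength = ss$longestBranchLength,
      SkeletonNumBranchPoints = ss$nBranchPoints,
      MeanIntensity = mean(iv), MaxIntensity = max(iv),
      SumIntensity = sum(iv), StdIntensity = stats::sd(iv),
      CentroidRow_px = mr, CentroidCol_px = mc,
      ImageBoundaryContact_Pixel = unname(contact[as.character(l)]),
      PixelSize = pixelSize)
  }
  if (!length(rows)) {
    out <- data.frame()
  } else out <- do.call(rbind, rows)
  out
}

#' Derived morphological features
#'
#' Adds the ten derived shape ratios to a cell record table, computed
#' exactly as defined:
#' Solidity = Area/ConvexArea; Roundness = Area/EllipsoidLongestAxisRadius^2;
#' Roundness2 = Area/EllipsoidShortestAxisRadius^2;
#' GeodesicElongation = GeodesicDiameter^2/Area;
#' AspectRatio = LargestInscribedCircleRadius^2/Area;
#' Circularity = Area/Perimeter^2;
#' Somaness = RadiusAtBrightestPoint_Pixel^2/Area;
#' Branchiness = SkeletonNumBranchPoints/GeodesicDiameter;
#' Straightness = SkeletonLongestBranchLength^2/Area;
#' Thickness = Area/SkeletonTotalLength^2.
#' (Roundness is the printed formula, without the pi normalization of the
#' classical roundness index.) A zero denominator yields NA, never 0.
#'
#' @param records data.frame from [measureCells()].
#' @return the table with the ten derived columns appended.
#' @export
deriveFeatures <- function(records) {
  if (!nrow(records)) return(records)
  base <- names(records)
  div <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  records <- within(records, {
    Solidity <- div(Area, ConvexArea)
    Roundness <- div(Area, EllipsoidLongestAxisRadius^2)
    Roundness2 <- div(Area, EllipsoidShortestAxisRadius^2)
    GeodesicElongation <- div(GeodesicDiameter^2, Area)
    AspectRatio <- div(LargestInscribedCircleRadius^2, Area)
    Circularity <- div(Area, Perimeter^2)
    Somaness <- div(RadiusAtBrightestPoint_Pixel^2, Area)
    Branchiness <- div(SkeletonNumBranchPoints, GeodesicDiameter)
    Straightness <- div(SkeletonLongestBranchLength^2, Area)
    Thickness <- div(Area, SkeletonTotalLength^2)
  })
  records[, c(base, derivedFeatureNames())]
}

#' Names of the derived feature columns
#' @return character vector of the ten derived feature names.
#' @export
derivedFeatureNames <- function() {
  c("Solidity", "Roundness", "Roundness2", "GeodesicElongation",
    "AspectRatio", "Circularity", "Somaness", "Branchiness",
    "Straightness", "Thickness")
}

#' Names of the base shape feature columns
#' @return character vector of base shape feature names (no intensity).
#' @export
baseShapeFeatureNames <- function() {
  c("Area", "ConvexArea", "Perimeter", "EllipsoidLongestAxisRadius",
    "EllipsoidShortestAxisRadius", "GeodesicDiameter",
    "LargestInscribedCircleRadius", "RadiusAtBrightestPoint_Pixel",
    "SkeletonTotalLength", "SkeletonLongestBranchLength",
    "SkeletonNumBranchPoints")
}

#' Drop incomplete (border-clipped) cells
#'
#' Cells whose number of border-contact pixels exceeds 1 percent of their
#' perimeter measured in pixels are considered incomplete and removed; the
#' comparison is strict ("above"), so a contact count exactly at 1 percent
#' is retained.
#'
#' @param records cell record table with `ImageBoundaryContact_Pixel`,
#'   `Perimeter` and `PixelSize` columns.
#' @param fraction perimeter fraction (default 0.01).
#' @return the retained records, unchanged.
#' @export
filterIncomplete <- function(records, fraction = 0.01) {
  if (!nrow(records)) return(records)
  perimPx <- records$Perimeter / records$PixelSize
  keep <- !(records$ImageBoundaryContact_Pixel > fraction * perimPx)
  records[keep, , drop = FALSE]
}
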