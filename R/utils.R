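# Internal helpers shared across modules. Images are numeric matrices
# (rows x cols); masks are integer matrices with 0 = background.

# raster-scan rank (row-major: row 1 left-to-right, then row 2, ...)
.rasterRank <- function(idx, dims) {
  r <- (idx - 1L) %% dims[1] + 1L
  c <- (idx - 1L) %/% dims[1] + 1L
  (r - 1) * dims[2] + c
}

# relabel positive labels to 1..K in raster-scan order of each label's
# first pixel; 0 stays 0
.compactLabels <- function(mask) {
  labs <- sort(unique(mask[mask > 0]))
  if (!length(labs)) return(mask)
  first <- vapply(labs, function(l) min(.rasterRank(which(mask == l), dim(mask))),
                  numeric(1))
  ord <- labs[order(first)]
  out <- mask
  for (k in seq_along(ord)) out[mask == ord[k]] <- k
  out
}

# 8-neighbour offsets (dr, dc)
.off8 <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
               dc = c(-1, 0, 1, -1, 1, -1, 0, 1))

# shift a matrix by (dr, dc), padding with `fill`
.shiftMat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# shoelace area of a polygon given vertex coordinates
.polygonArea <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# 4-connected (supercover-style) digital line between integer pixels;
# guaranteed to block 8-connected paths crossing it
.line4 <- function(r0, c0, r1, c1) {
  dc <- abs(c1 - c0); dr <- abs(r1 - r0)
  sc <- sign(c1 - c0); sr <- sign(r1 - r0)
  err <- dc - dr
  r <- r0; c <- c0
  pts <- list(c(r, c))
  while (r != r1 || c != c1) {
    e2 <- 2 * err
    stepC <- e2 > -dr && c != c1
    stepR <- e2 < dc && r != r1
    if (stepC && stepR) {
      # both axes advance: insert an axial intermediate so the digital
      # line is 4-connected and blocks 8-connected crossings
      pts[[length(pts) + 1L]] <- c(r, c + sc)
    }
    if (stepC) { err <- err - dr; c <- c + sc }
    if (stepR) { err <- err + dc; r <- r + sr }
    pts[[length(pts) + 1L]] <- c(r, c)
  }
  do.call(rbind, pts)
}

# rasterize a polyline (matrix of (row, col) vertices) into pixel indices
.rasterizePolyline <- function(vertices, dims) {
  stopifnot(ncol(vertices) == 2)
  v <- round(vertices)
  pts <- NULL
  for (i in seq_len(nrow(v) - 1)) {
    pts <- rbind(pts, .line4(v[i, 1], v[i, 2], v[i + 1, 1], v[i + 1, 2]))
  }
  if (is.null(pts)) pts <- v
  keep <- pts[, 1] >= 1 & pts[, 1] <= dims[1] & pts[, 2] >= 1 & pts[, 2] <= dims[2]
  pts <- pts[keep, , drop = FALSE]
  unique(pts[, 1] + (pts[, 2] - 1) * dims[1])
}

# crop a logical/integer mask to its bounding box with a 1-px pad
.cropMask <- function(mask, pad = 1L) {
  idx <- which(mask > 0)
  r <- (idx - 1L) %% nrow(mask) + 1L
  c <- (idx - 1L) %/% nrow(mask) + 1L
  rr <- range(r); cc <- range(c)
  sub <- matrix(0L, diff(rr) + 1 + 2 * pad, diff(cc) + 1 + 2 * pad)
  sub[cbind(r - rr[1] + 1 + pad, c - cc[1] + 1 + pad)] <- 1L
  list(mask = sub, rowOffset = rr[1] - 1L - pad, colOffset = cc[1] - 1L - pad)
}

# canonical quarter-turn orientation: among the 4 rotations of a binary
# matrix, the one whose vectorized bitmap (with dims prepended) is
# lexicographically smallest; makes direction-sensitive operators exactly
# invariant under 90-degree rotations
.canonicalRotation <- function(mask) {
  rots <- list(mask)
  m <- mask
  for (i in 2:4) {
    m <- t(m)[, rev(seq_len(nrow(m))), drop = FALSE]  # rotate 90 deg cw
    rots[[i]] <- m
  }
  keys <- vapply(rots, function(x)
    paste(c(dim(x), as.integer(x)), collapse = ","), character(1))
  rots[[order(keys)[1]]]
}

.isBinary <- function(m) all(m %in% c(0, 1))
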