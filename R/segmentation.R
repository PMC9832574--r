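# Segmentation of the reporter channel into curated label masks:
# edge-preserving smoothing, relative thresholding against the background
# level, 8-connected component labeling, size and skeleton-length filters,
# scripted mask edits and overlap-based tracking.

#' Segmentation configuration
#'
#' Parameters of the mask-generation pipeline. The defaults are the
#' settings the workflow was designed around: minimal cell size 200 um^2,
#' maximal skeleton length 450 um, relative intensity threshold 1.5, pixel
#' size 0.758 um.
#'
#' @param minCellSize minimum cell area (um^2); smaller components are
#'   discarded.
#' @param maxSkeletonLength maximum total skeleton length (um); longer
#'   components (typically merged clumps or debris strands) are discarded.
#'   `skeletonLengthMode` selects whether the filter uses the total length
#'   or only the longest branch.
#' @param thresholdFactor relative threshold: foreground is intensity >
#'   factor x background level.
#' @param diffusionIterations,diffusionConductance anisotropic-diffusion
#'   smoothing parameters (iterations; conductance scale in intensity
#'   units).
#' @param pixelSize micrometres per pixel.
#' @param skeletonLengthMode "total" or "longestBranch".
#' @return list of class `SegmentationConfig`.
#' @export
segmentationConfig <- function(minCellSize = 200, maxSkeletonLength = 450,
                               thresholdFactor = 1.5,
                               diffusionIterations = 10,
                               diffusionConductance = 5,
                               pixelSize = 0.758,
                               skeletonLengthMode = c("total", "longestBranch")) {
  skeletonLengthMode <- match.arg(skeletonLengthMode)
  vals <- c(minCellSize, maxSkeletonLength, thresholdFactor,
            diffusionIterations, diffusionConductance, pixelSize)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all segmentation parameters must be strictly positive")
  structure(list(minCellSize = minCellSize,
                 maxSkeletonLength = maxSkeletonLength,
                 thresholdFactor = thresholdFactor,
                 diffusionIterations = as.integer(diffusionIterations),
                 diffusionConductance = diffusionConductance,
                 pixelSize = pixelSize,
                 skeletonLengthMode = skeletonLengthMode),
            class = "SegmentationConfig")
}

#' Anisotropic diffusion smoothing
#'
#' Perona-Malik diffusion with the exponential conductance function
#' g(s) = exp(-(s/K)^2), explicit 4-neighbour scheme (time step 0.2) and
#' reflecting boundaries. Edges with contrast well above the conductance
#' scale K diffuse essentially not at all, so cell outlines survive while
#' noise is averaged out; because fluxes are antisymmetric the total
#' intensity is conserved.
#'
#' @param image non-negative numeric matrix.
#' @param iterations number of diffusion steps.
#' @param conductance conductance scale K in intensity units.
#' @return smoothed matrix, same dimensions.
#' @export
anisoDiffuse <- function(image, iterations = 10, conductance = 5) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  stopifnot(iterations >= 0, conductance > 0)
  u <- image
  lambda <- 0.2
  for (it in seq_len(iterations)) {
    nr <- nrow(u); nc <- ncol(u)
    # reflecting boundaries: difference to out-of-image neighbour is 0
    dN <- rbind(u[1, , drop = FALSE], u[-nr, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[nr, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -nc, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, nc, drop = FALSE]) - u
    flux <- dN * exp(-(dN / conductance)^2) + dS * exp(-(dS / conductance)^2) +
            dW * exp(-(dW / conductance)^2) + dE * exp(-(dE / conductance)^2)
    u <- u + lambda * flux
  }
  u
}

# background level estimate: value of the modal histogram bin (the field is
# mostly background at typical microglia densities), refined as the median
# of the pixels falling in that bin
.backgroundLevel <- function(image, nbins = 256) {
  rng <- range(image)
  if (diff(rng) == 0) return(rng[1])
  brk <- seq(rng[1], rng[2], length.out = nbins + 1)
  h <- findInterval(image, brk, all.inside = TRUE)
  tab <- tabulate(h, nbins)
  modal <- which.max(tab)
  stats::median(image[h == modal])
}

#' Relative threshold
#'
#' Binarizes a (smoothed) image at `factor` times the estimated background
#' level. The background level is the histogram mode of the image, which
#' is robust as long as background pixels dominate the field. A pixel is
#' foreground iff its intensity is strictly greater than
#' `factor * background`.
#'
#' @param image numeric matrix (usually the output of [anisoDiffuse()]).
#' @param factor relative threshold factor (default 1.5).
#' @return logical matrix (TRUE = foreground). The threshold used is
#'   attached as attribute `"threshold"`.
#' @export
relativeThreshold <- function(image, factor = 1.5) {
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  stopifnot(factor > 0)
  if (diff(range(image)) == 0) {
    warning("flat image: no contrast, returning empty foreground")
    out <- matrix(FALSE, nrow(image), ncol(image))
    attr(out, "threshold") <- NA_real_
    return(out)
  }
  bg <- .backgroundLevel(image)
  thr <- factor * bg
  out <- image > thr
  attr(out, "threshold") <- thr
  out
}

# 8-connected component labeling; labels 1..K in raster-scan order of each
# component's first pixel. EBImage's labeling is 4-connected, so labels
# that touch diagonally are merged by union-find first.
.label8 <- function(binary) {
  b <- matrix(as.numeric(binary > 0), nrow(binary), ncol(binary))
  lab <- EBImage::bwlabel(b)
  lab <- matrix(as.integer(lab), nrow(b), ncol(b))
  K <- max(lab)
  if (K > 1) {
    parent <- seq_len(K)
    findRoot <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    # diagonal neighbour pairs with different labels
    for (s in list(c(1, 1), c(-1, 1))) {
      a <- lab[seq_len(nrow(lab) - 1) + (s[1] == -1),
               seq_len(ncol(lab) - 1), drop = FALSE]
      bb <- lab[seq_len(nrow(lab) - 1) + (s[1] == 1),
                seq_len(ncol(lab) - 1) + 1, drop = FALSE]
      av <- as.vector(a); bv <- as.vector(bb)
      sel <- av > 0L & bv > 0L & av != bv
      av <- av[sel]; bv <- bv[sel]
      un <- !duplicated(av * (K + 1) + bv)
      pairs <- cbind(av[un], bv[un])
      for (i in seq_len(nrow(pairs))) {
        ra <- findRoot(pairs[i, 1]); rb <- findRoot(pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
    roots <- vapply(seq_len(K), findRoot, integer(1))
    lab[lab > 0] <- roots[lab[lab > 0]]
  }
  .compactLabels(lab)
}

#' Label a binary image and filter components
#'
#' Labels 8-connected foreground components (labels 1..K in raster-scan
#' order of each component's first pixel), removes components smaller than
#' the minimum cell area or with skeleton length above the maximum, and
#' re-compacts labels.
#'
#' @param binary logical/0-1 matrix.
#' @param config a [segmentationConfig()].
#' @return integer label mask. Attribute `"removed"` lists the counts
#'   removed by each filter.
#' @export
labelAndFilter <- function(binary, config = segmentationConfig()) {
  stopifnot(inherits(config, "SegmentationConfig"))
  lab <- .label8(binary)
  K <- max(lab)
  if (K == 0) return(lab)
  px2 <- config$pixelSize^2
  removedSize <- 0L; removedSkel <- 0L
  for (k in seq_len(K)) {
    pix <- which(lab == k)
    areaUm2 <- length(pix) * px2
    if (areaUm2 < config$minCellSize) {
      lab[pix] <- 0L; removedSize <- removedSize + 1L
      next
    }
    cr <- .cropMask(lab == k)
    ss <- skeletonStats(cr$mask, config$pixelSize)
    len <- if (config$skeletonLengthMode == "total") ss$totalLength
           else ss$longestBranchLength
    if (len > config$maxSkeletonLength) {
      lab[pix] <- 0L; removedSkel <- removedSkel + 1L
    }
  }
  out <- .compactLabels(lab)
  attr(out, "removed") <- c(size = removedSize, skeleton = removedSkel)
  out
}

#' Segment one intensity frame
#'
#' Full mask generation for a frame: anisotropic-diffusion smoothing,
#' relative thresholding, 8-connected labeling and size/skeleton filtering.
#'
#' @param image numeric matrix or a [Field-class] (red channel is used).
#' @param config a [segmentationConfig()].
#' @return integer label mask.
#' @export
segmentFrame <- function(image, config = segmentationConfig()) {
  if (is(image, "Field")) image <- redChannel(image)
  sm <- anisoDiffuse(image, config$diffusionIterations,
                     config$diffusionConductance)
  fg <- relativeThreshold(sm, config$thresholdFactor)
  labelAndFilter(fg, config)
}

#' Mask edit records
#'
#' Scripted replacements for interactive mask curation: a split removes a
#' dividing polyline from one label and relabels the remaining pieces; a
#' merge gives a set of labels one shared label.
#'
#' @param label label id to split.
#' @param polyline numeric matrix of (row, col) vertices of the dividing
#'   line (rasterized 4-connected, so it severs 8-connected components).
#' @return list of class `MaskEdit`.
#' @export
maskEditSplit <- function(label, polyline) {
  stopifnot(is.numeric(label), length(label) == 1, ncol(polyline) == 2,
            nrow(polyline) >= 2)
  structure(list(kind = "split", label = as.integer(label),
                 polyline = polyline), class = "MaskEdit")
}

#' @rdname maskEditSplit
#' @param labels integer vector (>= 2) of labels to merge.
#' @export
maskEditMerge <- function(labels) {
  stopifnot(length(labels) >= 2)
  structure(list(kind = "merge", labels = as.integer(labels)),
            class = "MaskEdit")
}

#' Apply scripted mask edits
#'
#' @param mask integer label mask.
#' @param edits list of [maskEditSplit()] / [maskEditMerge()] records,
#'   applied in order. Edits must reference labels that exist at the time
#'   they are applied. A split whose polyline does not intersect the label
#'   is a no-op with a warning. Merged labels take the smallest id of the
#'   set; split pieces get fresh ids above the current maximum, in
#'   raster-scan order.
#' @return edited label mask.
#' @export
applyEdits <- function(mask, edits) {
  for (e in edits) {
    stopifnot(inherits(e, "MaskEdit"))
    if (e$kind == "merge") {
      if (!all(e$labels %in% mask))
        stop("merge references missing label(s): ",
             paste(setdiff(e$labels, unique(as.vector(mask))), collapse = ", "))
      mask[mask %in% e$labels] <- min(e$labels)
    } else {
      if (!e$label %in% mask)
        stop("split references missing label ", e$label)
      line <- .rasterizePolyline(e$polyline, dim(mask))
      cut <- intersect(line, which(mask == e$label))
      if (!length(cut)) {
        warning("split polyline does not intersect label ", e$label,
                "; no-op")
        next
      }
      piece <- mask == e$label
      piece[cut] <- FALSE
      mask[mask == e$label] <- 0L
      sub <- .label8(piece)
      nsub <- max(sub)
      if (nsub > 0) {
        base <- max(mask)
        mask[sub > 0] <- sub[sub > 0] + base
      }
    }
  }
  mask
}

#' Track label masks over time
#'
#' Propagates cell identities through a time-lapse by greedy maximal-
#' overlap linking: each cell at frame t inherits the id of the frame t-1
#' cell it overlaps most, provided the overlap is at least `minOverlap` of
#' the smaller of the two areas; the matching is injective (greedy in
#' descending overlap). Unmatched cells receive fresh, never reused ids.
#'
#' @param masks list of integer label masks (ordered frames).
#' @param minOverlap minimum overlap fraction of the smaller area
#'   (default 0.2).
#' @return list of relabeled masks with temporally consistent ids.
#' @export
trackMasks <- function(masks, minOverlap = 0.2) {
  stopifnot(length(masks) >= 1)
  out <- vector("list", length(masks))
  out[[1]] <- masks[[1]]
  nextId <- max(0L, max(masks[[1]]))
  for (t in seq_along(masks)[-1]) {
    prev <- out[[t - 1]]; cur <- masks[[t]]
    curLabs <- setdiff(sort(unique(as.vector(cur))), 0L)
    prevLabs <- setdiff(sort(unique(as.vector(prev))), 0L)
    prevArea <- vapply(prevLabs, function(l) sum(prev == l), numeric(1))
    names(prevArea) <- prevLabs
    cand <- list()
    for (l in curLabs) {
      pix <- cur == l
      areaC <- sum(pix)
      ov <- table(prev[pix & prev > 0])
      for (p in names(ov)) {
        frac <- ov[[p]] / min(areaC, prevArea[[p]])
        if (frac >= minOverlap)
          cand[[length(cand) + 1L]] <- data.frame(
            cur = l, prev = as.integer(p), overlap = ov[[p]], frac = frac)
      }
    }
    newMask <- matrix(0L, nrow(cur), ncol(cur))
    assigned <- integer(0); usedPrev <- integer(0)
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      cand <- cand[order(-cand$overlap, cand$cur, cand$prev), , drop = FALSE]
      for (i in seq_len(nrow(cand))) {
        if (cand$cur[i] %in% assigned || cand$prev[i] %in% usedPrev) next
        newMask[cur == cand$cur[i]] <- cand$prev[i]
        assigned <- c(assigned, cand$cur[i])
        usedPrev <- c(usedPrev, cand$prev[i])
      }
    }
    for (l in setdiff(curLabs, assigned)) {
      nextId <- nextId + 1L
      newMask[cur == l] <- nextId
    }
    nextId <- max(nextId, max(newMask))
    out[[t]] <- newMask
  }
  out
}
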