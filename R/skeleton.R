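# Skeletonization by iterative thinning and skeleton graph statistics.
# Length convention (stated because different tools differ): the skeleton
# is treated as a pixel graph with 8-adjacency; each adjacent pixel pair
# contributes one step of length 1 (axial) or sqrt(2) (diagonal) times the
# pixel size. Diagonal steps that merely cut the corner of two axial steps
# are dropped so triangles are not double-counted.

#' Thin a binary mask to a unit-width skeleton
#'
#' Zhang-Suen thinning. The input is reduced to an 8-connected, one pixel
#' wide skeleton; connectivity of each object is preserved.
#'
#' @param mask binary matrix (0/1 or logical).
#' @return integer matrix of the same size, 1 on the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  if (!sum(m)) return(m)
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours P2..P9 clockwise from north; row-1 = north
      P2 <- .shiftMat(m,  1,  0); P3 <- .shiftMat(m,  1, -1)
      P4 <- .shiftMat(m,  0, -1); P5 <- .shiftMat(m, -1, -1)
      P6 <- .shiftMat(m, -1,  0); P7 <- .shiftMat(m, -1,  1)
      P8 <- .shiftMat(m,  0,  1); P9 <- .shiftMat(m,  1,  1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
           (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
           (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (step == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# skeleton pixel graph: vertices = skeleton pixels, edges = 8-adjacency
# with weights 1 / sqrt(2); corner-cutting diagonal edges removed
.skeletonGraph <- function(skel) {
  idx <- which(skel > 0)
  n <- length(idx)
  if (n == 0) return(NULL)
  dims <- dim(skel)
  id <- matrix(0L, dims[1], dims[2]); id[idx] <- seq_len(n)
  rr <- (idx - 1L) %% dims[1] + 1L
  cc <- (idx - 1L) %/% dims[1] + 1L
  el <- list(); wl <- list()
  steps <- list(c(0, 1, 1), c(1, 0, 1), c(1, 1, sqrt(2)), c(-1, 1, sqrt(2)))
  inSkel <- function(r, c) {
    ok <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2]
    ok[ok] <- skel[cbind(r[ok], c[ok])] > 0
    ok
  }
  for (s in steps) {
    r2 <- rr + s[1]; c2 <- cc + s[2]
    ok <- inSkel(r2, c2)
    if (s[3] > 1) {
      # drop the diagonal if an axial 2-step pathway exists (the diagonal
      # is redundant and would create spurious triangles/junctions)
      corner <- inSkel(rr + s[1], cc) | inSkel(rr, cc + s[2])
      ok <- ok & !corner
    }
    if (any(ok))  {
      el[[length(el) + 1L]] <- cbind(id[cbind(rr[ok], cc[ok])],
                                     id[cbind(r2[ok], c2[ok])])
      wl[[length(wl) + 1L]] <- rep(s[3], sum(ok))
    }
  }
  if (!length(el)) {
    g <- igraph::make_empty_graph(n, directed = FALSE)
  } else {
    g <- igraph::graph_from_edgelist(do.call(rbind, el), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, n - igraph::vcount(g)))
    igraph::E(g)$weight <- unlist(wl)
  }
  list(graph = g, idx = idx, row = rr, col = cc)
}

# iteratively remove leaf branches (endpoint to junction) shorter than
# prunePx: discrete thinning leaves short spurs wherever the boundary is
# jagged, and these would otherwise inflate branch-point counts
.pruneSpurs <- function(g, prunePx) {
  repeat {
    deg <- igraph::degree(g)
    if (!any(deg >= 3)) return(g)
    drop <- integer(0)
    for (e in which(deg == 1)) {
      path <- e; v <- e; prev <- -1L; len <- 0
      repeat {
        nb <- setdiff(as.integer(igraph::neighbors(g, v)), prev)
        if (!length(nb)) { path <- NULL; break }       # isolated path end
        nxt <- nb[1]
        len <- len + igraph::E(g)$weight[igraph::get_edge_ids(g, c(v, nxt))]
        if (deg[nxt] >= 3) break                        # reached a junction
        if (deg[nxt] == 1) { path <- NULL; break }      # pure path, keep
        path <- c(path, nxt); prev <- v; v <- nxt
      }
      if (!is.null(path) && len < prunePx) drop <- union(drop, path)
    }
    if (!length(drop)) return(g)
    g <- igraph::delete_vertices(g, drop)
  }
}

#' Skeleton statistics of a binary shape
#'
#' Thins the mask and measures the skeleton: total length, longest branch
#' length and the number of branch points. Short spur branches (below
#' `prunePx` pixels) are pruned first; they are thinning artifacts of
#' jagged boundaries, not processes. Branch points are junction clusters:
#' connected groups of skeleton pixels with three or more skeleton
#' neighbours count as one junction. Branches are the skeleton segments
#' obtained by removing the junction pixels; each branch length includes
#' its connecting steps into the adjacent junctions.
#'
#' @param mask binary matrix (a single shape).
#' @param pixelSize micrometres per pixel (1 = report in pixels).
#' @param prunePx spur-pruning threshold in pixels (default 6).
#' @return list: `totalLength`, `longestBranchLength`, `nBranchPoints`,
#'   `skeleton` (the thinned matrix, before pruning).
#' @export
skeletonStats <- function(mask, pixelSize = 1, prunePx = 6) {
  skel <- skeletonize(mask)
  sg <- .skeletonGraph(skel)
  if (is.null(sg))
    return(list(totalLength = 0, longestBranchLength = 0,
                nBranchPoints = 0L, skeleton = skel))
  g <- sg$graph
  if (igraph::ecount(g) == 0)
    return(list(totalLength = 0, longestBranchLength = 0,
                nBranchPoints = 0L, skeleton = skel))
  g <- .pruneSpurs(g, prunePx)
  if (igraph::ecount(g) == 0)
    return(list(totalLength = 0, longestBranchLength = 0,
                nBranchPoints = 0L, skeleton = skel))
  deg <- igraph::degree(g)
  total <- sum(igraph::E(g)$weight)
  junction <- which(deg >= 3)
  if (length(junction)) {
    jg <- igraph::induced_subgraph(g, junction)
    nBranch <- igraph::count_components(jg)
  } else nBranch <- 0L
  # branch decomposition: remove junction pixels, measure remaining segments
  if (length(junction)) {
    keep <- setdiff(seq_len(igraph::vcount(g)), junction)
    sub <- igraph::induced_subgraph(g, keep)
    comp <- igraph::components(sub)
    segLen <- rep(0, comp$no)
    if (igraph::ecount(sub) > 0) {
      ee <- igraph::ends(sub, igraph::E(sub), names = FALSE)
      for (i in seq_len(nrow(ee))) {
        cid <- comp$membership[ee[i, 1]]
        segLen[cid] <- segLen[cid] + igraph::E(sub)$weight[i]
      }
    }
    # add connector steps from each segment into adjacent junctions
    inc <- igraph::ends(g, igraph::E(g), names = FALSE)
    w <- igraph::E(g)$weight
    isJ <- logical(igraph::vcount(g)); isJ[junction] <- TRUE
    mapKeep <- integer(igraph::vcount(g)); mapKeep[keep] <- seq_along(keep)
    for (i in seq_len(nrow(inc))) {
      a <- inc[i, 1]; b <- inc[i, 2]
      if (xor(isJ[a], isJ[b])) {
        v <- if (isJ[a]) b else a
        cid <- comp$membership[mapKeep[v]]
        segLen[cid] <- segLen[cid] + w[i]
      }
    }
    longest <- if (length(segLen)) max(segLen) else 0
  } else {
    # unbranched skeleton: the single branch is the whole skeleton
    longest <- total
  }
  list(totalLength = total * pixelSize,
       longestBranchLength = min(longest, total) * pixelSize,
       nBranchPoints = as.integer(nBranch), skeleton = skel)
}
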