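# Independent oracles used by the tests. These deliberately re-derive
# quantities with different algorithms/code paths than the package.

# --- Guo-Hall thinning (independent of the package's Zhang-Suen) --------
oracleThin <- function(mask) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  nb <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (iter in 0:1) {
      p2 <- nb(m, 1, 0);  p3 <- nb(m, 1, -1); p4 <- nb(m, 0, -1)
      p5 <- nb(m, -1, -1); p6 <- nb(m, -1, 0); p7 <- nb(m, -1, 1)
      p8 <- nb(m, 0, 1);  p9 <- nb(m, 1, 1)
      C <- ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
           ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2))
      N1 <- (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8)
      N2 <- (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9)
      N <- pmin(N1, N2)
      Ocond <- if (iter == 0) (p2 | p3 | (!p5)) & p4 else (p6 | p7 | (!p9)) & p8
      del <- m == 1 & C == 1 & N >= 2 & N <= 3 & !Ocond
      if (any(del)) { m[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# junction clusters of a unit-width skeleton: neighbour counting done
# directly on the bitmap (corner-redundant diagonals ignored), clusters
# merged by flood fill
oracleJunctionCount <- function(skel, prunePx = 6) {
  pts <- which(skel > 0)
  if (!length(pts)) return(0L)
  nr <- nrow(skel)
  coord <- cbind((pts - 1L) %% nr + 1L, (pts - 1L) %/% nr + 1L)
  key <- function(r, c) paste(r, c)
  set <- new.env(hash = TRUE)
  for (i in seq_len(nrow(coord))) assign(key(coord[i, 1], coord[i, 2]), i, set)
  has <- function(r, c) !is.null(get0(key(r, c), envir = set))
  # adjacency without corner-redundant diagonals
  neighbours <- function(r, c) {
    res <- list()
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
      if (has(r + d[1], c + d[2])) res[[length(res) + 1]] <- c(r + d[1], c + d[2])
    for (d in list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
      if (has(r + d[1], c + d[2]) && !has(r + d[1], c) && !has(r, c + d[2]))
        res[[length(res) + 1]] <- c(r + d[1], c + d[2])
    res
  }
  deg <- integer(nrow(coord))
  adj <- vector("list", nrow(coord))
  for (i in seq_len(nrow(coord))) {
    nbs <- neighbours(coord[i, 1], coord[i, 2])
    deg[i] <- length(nbs)
    adj[[i]] <- vapply(nbs, function(p) get(key(p[1], p[2]), envir = set),
                       integer(1))
  }
  stepLen <- function(i, j) {
    if (sum(abs(coord[i, ] - coord[j, ])) == 2) sqrt(2) else 1
  }
  # prune leaf branches shorter than prunePx (mirrors the stated length
  # convention, implemented by direct walking)
  alive <- rep(TRUE, nrow(coord))
  repeat {
    degA <- vapply(seq_along(adj), function(i)
      if (alive[i]) sum(alive[adj[[i]]]) else 0L, numeric(1))
    if (!any(degA >= 3)) break
    removed <- FALSE
    for (e in which(alive & degA == 1)) {
      path <- e; v <- e; prev <- -1L; len <- 0; ok <- FALSE
      repeat {
        nxt <- setdiff(adj[[v]][alive[adj[[v]]]], prev)
        if (!length(nxt)) break
        nxt <- nxt[1]
        len <- len + stepLen(v, nxt)
        if (degA[nxt] >= 3) { ok <- TRUE; break }
        if (degA[nxt] == 1) break
        path <- c(path, nxt); prev <- v; v <- nxt
      }
      if (ok && len < prunePx) { alive[path] <- FALSE; removed <- TRUE }
    }
    if (!removed) break
  }
  degA <- vapply(seq_along(adj), function(i)
    if (alive[i]) sum(alive[adj[[i]]]) else 0L, numeric(1))
  junction <- which(alive & degA >= 3)
  if (!length(junction)) return(0L)
  # cluster junction pixels by 8-adjacency flood fill
  lab <- integer(length(junction)); cur <- 0L
  names(lab) <- junction
  for (j in junction) {
    if (lab[as.character(j)] != 0L) next
    cur <- cur + 1L
    queue <- j
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (lab[as.character(v)] != 0L) next
      lab[as.character(v)] <- cur
      nxt <- intersect(adj[[v]], junction)
      queue <- c(queue, nxt[lab[as.character(nxt)] == 0L])
    }
  }
  max(lab)
}

# --- brute-force geodesic diameter on small masks -----------------------
# Dijkstra written directly on the pixel grid (no igraph), same step set
# as documented: axial 1, diagonal sqrt(2), knight sqrt(5) with both
# stepping stones inside
oracleGeodesicDiameter <- function(mask) {
  idx <- which(mask > 0)
  n <- length(idx)
  if (n <= 1) return(0)
  nr <- nrow(mask); ncl <- ncol(mask)
  rr <- (idx - 1L) %% nr + 1L; cc <- (idx - 1L) %/% nr + 1L
  id <- matrix(0L, nr, ncl); id[idx] <- seq_len(n)
  inM <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= ncl && mask[r, c] > 0
  moves <- rbind(c(0, 1, 1), c(0, -1, 1), c(1, 0, 1), c(-1, 0, 1),
                 c(1, 1, sqrt(2)), c(1, -1, sqrt(2)), c(-1, 1, sqrt(2)),
                 c(-1, -1, sqrt(2)),
                 c(1, 2, sqrt(5)), c(2, 1, sqrt(5)), c(-1, 2, sqrt(5)),
                 c(-2, 1, sqrt(5)), c(1, -2, sqrt(5)), c(2, -1, sqrt(5)),
                 c(-1, -2, sqrt(5)), c(-2, -1, sqrt(5)))
  best <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    done <- rep(FALSE, n)
    repeat {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u]) || all(done)) break
      done[u] <- TRUE
      for (k in seq_len(nrow(moves))) {
        r2 <- rr[u] + moves[k, 1]; c2 <- cc[u] + moves[k, 2]
        if (!inM(r2, c2)) next
        if (moves[k, 3] > 2) {
          s1r <- rr[u] + round(moves[k, 1] / 2); s1c <- cc[u] + round(moves[k, 2] / 2)
          s2r <- rr[u] + moves[k, 1] - round(moves[k, 1] / 2)
          s2c <- cc[u] + moves[k, 2] - round(moves[k, 2] / 2)
          if (!inM(s1r, s1c) || !inM(s2r, s2c)) next
        }
        v <- id[r2, c2]
        if (dist[u] + moves[k, 3] < dist[v]) dist[v] <- dist[u] + moves[k, 3]
      }
      if (all(done | !is.finite(dist))) break
    }
    best <- max(best, max(dist[is.finite(dist)]))
  }
  best
}

# --- auto-threshold oracles on a 256-bin histogram ----------------------
oracleIsodata <- function(counts, mids) {
  t <- sum(counts * mids) / sum(counts)
  for (i in 1:500) {
    lo <- mids <= t
    mLo <- sum(counts[lo] * mids[lo]) / max(1, sum(counts[lo]))
    mHi <- sum(counts[!lo] * mids[!lo]) / max(1, sum(counts[!lo]))
    tn <- (mLo + mHi) / 2
    if (abs(tn - t) < 1e-12) break
    t <- tn
  }
  t
}

oracleHuang <- function(counts, mids) {
  C <- diff(range(mids))
  n <- length(mids)
  S <- rep(NA_real_, n - 1)
  for (k in seq_len(n - 1)) {
    w0 <- sum(counts[1:k]); w1 <- sum(counts) - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / w0
    mu1 <- sum(counts[(k + 1):n] * mids[(k + 1):n]) / w1
    tot <- 0
    for (g in seq_len(n)) {
      if (counts[g] == 0) next
      m <- if (g <= k) mu0 else mu1
      u <- 1 / (1 + abs(mids[g] - m) / C)
      h <- if (u >= 1) 0 else -(u * log(u) + (1 - u) * log(1 - u))
      tot <- tot + counts[g] * h
    }
    S[k] <- tot
  }
  k <- which.min(S)
  (mids[k] + mids[k + 1]) / 2
}

# direct arithmetic chi-squared on a 2 x C table
oracleChisq <- function(O) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  sum((O - E)^2 / E)
}

# independent derived-feature recomputation from base columns
oracleDerive <- function(rec) {
  sdiv <- function(a, b) ifelse(b == 0, NA_real_, a / b)
  data.frame(
    Solidity = sdiv(rec$Area, rec$ConvexArea),
    Roundness = sdiv(rec$Area, rec$EllipsoidLongestAxisRadius^2),
    Roundness2 = sdiv(rec$Area, rec$EllipsoidShortestAxisRadius^2),
    GeodesicElongation = sdiv(rec$GeodesicDiameter^2, rec$Area),
    AspectRatio = sdiv(rec$LargestInscribedCircleRadius^2, rec$Area),
    Circularity = sdiv(rec$Area, rec$Perimeter^2),
    Somaness = sdiv(rec$RadiusAtBrightestPoint_Pixel^2, rec$Area),
    Branchiness = sdiv(rec$SkeletonNumBranchPoints, rec$GeodesicDiameter),
    Straightness = sdiv(rec$SkeletonLongestBranchLength^2, rec$Area),
    Thickness = sdiv(rec$Area, rec$SkeletonTotalLength^2))
}

# serpentine ribbon: one connected 3-px-wide path of known length
snakeMask <- function(dims = c(160, 160), margin = 8, rowStep = 10,
                      nPx = 800) {
  sn <- matrix(FALSE, dims[1], dims[2])
  r <- margin; c <- margin; dir <- 1
  for (i in seq_len(nPx)) {
    sn[r + (-1:1), c] <- TRUE
    if ((c + dir) > (dims[2] - margin) || (c + dir) < margin) {
      # turn: paint the vertical connector, then reverse
      sn[r:(r + rowStep) + 1, c + (-1:0)] <- TRUE
      r <- r + rowStep
      dir <- -dir
    } else c <- c + dir
  }
  sn
}

# digital disk helper
makeDisk <- function(radiusPx, pad = 5) {
  n <- 2 * (radiusPx + pad) + 1
  ctr <- radiusPx + pad + 1
  m <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if ((i - ctr)^2 + (j - ctr)^2 <= radiusPx^2) m[i, j] <- 1L
  m
}

# per-label Jaccard of a segmentation against a truth mask, matched by
# maximal overlap
truthJaccard <- function(mask, truth) {
  vapply(setdiff(sort(unique(as.vector(truth))), 0L), function(k) {
    tpx <- truth == k
    ov <- table(mask[tpx][mask[tpx] > 0])
    if (!length(ov)) return(0)
    m <- as.integer(names(ov)[which.max(ov)])
    sum(tpx & mask == m) / sum(tpx | mask == m)
  }, numeric(1))
}
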