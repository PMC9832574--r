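# Synthetic two-channel fields: parameterized microglia archetypes in the
# red (reporter) channel and punctate debris particles in the green
# (nucleic-acid stain) channel, with full ground truth. Shapes are defined
# in continuous micrometre coordinates and sampled at pixel centers.

# run code under a seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, fun) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fun()
}

# per-class geometry defaults (micrometres). The source descriptions of the
# seven morphologies are qualitative; these numbers are this package's own
# construction, chosen so the classes are well separated in feature space.
# somaAspect is the soma ellipse axis ratio (area-preserving).
.archetypeDefaults <- function() {
  list(
    round                = list(somaRadius = 9,    nProcesses = 0, processLength = 0,  processWidth = 0,   branchPoints = 0, somaAspect = 1.00, intensityProfile = "uniform"),
    inflamed_ameboid     = list(somaRadius = 11.3, nProcesses = 4, processLength = 6,  processWidth = 5,   branchPoints = 0, somaAspect = 1.00, intensityProfile = "uniform"),
    fried_egg            = list(somaRadius = 16,   nProcesses = 0, processLength = 0,  processWidth = 0,   branchPoints = 0, somaAspect = 1.45, intensityProfile = "bright_center"),
    inflamed_fried_egg   = list(somaRadius = 22.6, nProcesses = 3, processLength = 5,  processWidth = 8,   branchPoints = 0, somaAspect = 1.45, intensityProfile = "bright_center"),
    hypertrophic         = list(somaRadius = 9,    nProcesses = 5, processLength = 20, processWidth = 2.5, branchPoints = 2, somaAspect = 1.30, intensityProfile = "uniform"),
    inflamed_hypertrophic = list(somaRadius = 12.7, nProcesses = 5, processLength = 40, processWidth = 4,  branchPoints = 4, somaAspect = 1.30, intensityProfile = "uniform"),
    bipolar              = list(somaRadius = 6,    nProcesses = 2, processLength = 30, processWidth = 1.8, branchPoints = 0, somaAspect = 1.10, intensityProfile = "uniform")
  )
}

#' Specification of one synthetic cell shape
#'
#' Describes one cell of a given morphology class as a soma ellipse plus
#' capsule-shaped processes with optional side branches. All lengths are in
#' micrometres. Defaults come from the per-class archetype table (see
#' [archetypeSpec()]); the same spec and seed always render the same shape.
#'
#' @param className one of [morphologyClasses()].
#' @param somaRadius equivalent soma radius (um); the soma is drawn as an
#'   area-preserving ellipse with the class's axis ratio.
#' @param nProcesses number of processes. Bipolar cells must have exactly 2
#'   (unbranched); round and fried-egg cells must have 0.
#' @param processLength,processWidth process capsule length and width (um).
#' @param branchPoints number of side branches (each adds one skeleton
#'   junction); must be 0 for unbranched classes.
#' @param intensityProfile "uniform" or "bright_center".
#' @param somaAspect soma ellipse axis ratio (>= 1).
#' @param seed integer controlling the shape's random orientation/jitter.
#' @return A list of class `ShapeSpec`.
#' @export
shapeSpec <- function(className, somaRadius, nProcesses, processLength,
                      processWidth, branchPoints = 0,
                      intensityProfile = c("uniform", "bright_center"),
                      somaAspect = 1, seed = 1L) {
  className <- match.arg(className, morphologyClasses())
  intensityProfile <- match.arg(intensityProfile)
  if (!is.finite(somaRadius) || somaRadius <= 0)
    stop("somaRadius must be > 0")
  if (nProcesses < 0 || processLength < 0 || processWidth < 0 || branchPoints < 0)
    stop("process parameters and branchPoints must be >= 0")
  if (className == "bipolar" && (nProcesses != 2 || branchPoints != 0))
    stop("bipolar cells have exactly 2 unbranched processes")
  if (className %in% c("round", "fried_egg") && nProcesses != 0)
    stop(className, " cells have 0 processes")
  if (nProcesses > 0 && (processLength <= 0 || processWidth <= 0))
    stop("processes require positive length and width")
  if (branchPoints > 0 && nProcesses == 0)
    stop("branchPoints require at least one process")
  structure(list(className = className, somaRadius = somaRadius,
                 nProcesses = as.integer(nProcesses),
                 processLength = processLength, processWidth = processWidth,
                 branchPoints = as.integer(branchPoints),
                 intensityProfile = intensityProfile,
                 somaAspect = somaAspect, seed = as.integer(seed)),
            class = "ShapeSpec")
}

#' Archetype shape specification for a morphology class
#'
#' Returns the default [shapeSpec()] for a class, optionally with
#' multiplicative jitter on soma radius and process length so that fields
#' contain within-class variation.
#'
#' @param className one of [morphologyClasses()].
#' @param seed integer seed (controls jitter and rendering orientation).
#' @param jitter relative half-width of the uniform size jitter (default 0,
#'   i.e. the exact archetype).
#' @return A `ShapeSpec`.
#' @export
archetypeSpec <- function(className, seed = 1L, jitter = 0) {
  className <- match.arg(className, morphologyClasses())
  d <- .archetypeDefaults()[[className]]
  f <- if (jitter > 0)
    .withSeed(seed * 7919L + 13L, function() runif(2, 1 - jitter, 1 + jitter))
  else c(1, 1)
  shapeSpec(className,
            somaRadius = d$somaRadius * f[1],
            nProcesses = d$nProcesses,
            processLength = d$processLength * f[2],
            processWidth = d$processWidth,
            branchPoints = d$branchPoints,
            intensityProfile = d$intensityProfile,
            somaAspect = d$somaAspect, seed = seed)
}

# squared distance from points (x, y) to segment p0->p1
.segDist2 <- function(x, y, p0, p1) {
  vx <- p1[1] - p0[1]; vy <- p1[2] - p0[2]
  l2 <- vx * vx + vy * vy
  if (l2 == 0) return((x - p0[1])^2 + (y - p0[2])^2)
  t <- pmin(1, pmax(0, ((x - p0[1]) * vx + (y - p0[2]) * vy) / l2))
  (x - (p0[1] + t * vx))^2 + (y - (p0[2] + t * vy))^2
}

#' Render one cell
#'
#' Draws the cell described by a [shapeSpec()] in continuous coordinates
#' and samples it at pixel centers, returning a connected binary mask and a
#' non-negative intensity patch (1 inside the cell, raised towards the soma
#' center for the "bright_center" profile).
#'
#' @param spec a `ShapeSpec`.
#' @param pixelSize pixel edge length in micrometres.
#' @return list with `mask` (0/1 integer matrix), `intensity` (numeric
#'   matrix), `center` (row, col of the soma center within the patch) and
#'   `truth` (soma/process parameters actually used).
#' @export
renderCell <- function(spec, pixelSize = 0.758) {
  stopifnot(inherits(spec, "ShapeSpec"), pixelSize > 0)
  d <- spec
  .withSeed(d$seed, function() {
    a <- d$somaRadius * sqrt(d$somaAspect)   # soma semi-axes (um)
    b <- d$somaRadius / sqrt(d$somaAspect)
    phi <- runif(1, 0, pi)                    # soma orientation
    # process geometry
    segs <- list()
    if (d$nProcesses > 0) {
      base <- runif(1, 0, 2 * pi)
      for (i in seq_len(d$nProcesses)) {
        theta <- if (d$className == "bipolar") base + (i - 1) * pi
                 else base + 2 * pi * (i - 1) / d$nProcesses +
                      runif(1, -0.25, 0.25) * 2 * pi / d$nProcesses
        # soma boundary radius along theta
        ct <- cos(theta - phi); st <- sin(theta - phi)
        rb <- 1 / sqrt((ct / a)^2 + (st / b)^2)
        len <- d$processLength * runif(1, 0.9, 1.1)
        p0 <- 0.85 * rb * c(cos(theta), sin(theta))
        p1 <- p0 + (0.15 * rb + len) * c(cos(theta), sin(theta))
        segs[[length(segs) + 1L]] <- list(p0 = p0, p1 = p1,
                                          w = d$processWidth, proc = i)
      }
      # side branches: round-robin over processes, alternating sides
      if (d$branchPoints > 0) {
        nmain <- d$nProcesses
        cnt <- integer(nmain)
        for (j in seq_len(d$branchPoints)) {
          i <- ((j - 1) %% nmain) + 1L
          cnt[i] <- cnt[i] + 1L
          s <- segs[[i]]
          frac <- 0.40 + 0.25 * (cnt[i] - 1)
          anchor <- s$p0 + frac * (s$p1 - s$p0)
          dir0 <- atan2(s$p1[2] - s$p0[2], s$p1[1] - s$p0[1])
          side <- if (j %% 2 == 0) 1 else -1
          ang <- dir0 + side * (runif(1, 40, 55) * pi / 180)
          blen <- 0.5 * sqrt(sum((s$p1 - s$p0)^2))
          q1 <- anchor + blen * c(cos(ang), sin(ang))
          segs[[length(segs) + 1L]] <- list(p0 = anchor, p1 = q1,
                                            w = 0.8 * s$w, proc = i)
        }
      }
    }
    # patch extent
    ext <- a + d$processWidth
    for (s in segs) ext <- max(ext, sqrt(sum(s$p1^2)) + s$w)
    hpx <- ceiling(ext / pixelSize) + 2L
    n <- 2L * hpx + 1L
    ctr <- hpx + 1L
    xs <- (seq_len(n) - ctr) * pixelSize   # columns -> x
    ys <- (seq_len(n) - ctr) * pixelSize   # rows    -> y
    X <- matrix(xs, n, n, byrow = TRUE)
    Y <- matrix(ys, n, n)
    cp <- cos(phi); sp <- sin(phi)
    u <- (X * cp + Y * sp) / a
    v <- (-X * sp + Y * cp) / b
    inside <- (u * u + v * v) <= 1
    for (s in segs)
      inside <- inside | (.segDist2(X, Y, s$p0, s$p1) <= (s$w / 2)^2)
    mask <- matrix(0L, n, n); mask[inside] <- 1L
    intensity <- matrix(0, n, n)
    if (d$intensityProfile == "bright_center") {
      sig <- d$somaRadius / 2
      intensity[inside] <- 1 + 1.5 * exp(-(X[inside]^2 + Y[inside]^2) / (2 * sig^2))
    } else {
      intensity[inside] <- 1
    }
    list(mask = mask, intensity = intensity, center = c(ctr, ctr),
         truth = list(className = d$className, somaSemiAxes = c(a, b),
                      orientation = phi, nSegments = length(segs),
                      branchPoints = d$branchPoints, areaPx = sum(mask)))
  })
}

#' Specification of one synthetic field
#'
#' Describes a two-channel acquisition: cell shapes with positions in the
#' red channel, debris particles in the green channel, constant background
#' with optional additive Gaussian noise. Cells are rendered at
#' `backgroundLevel + cellIntensity * profile`; particles at
#' `backgroundLevel + particleIntensity`.
#'
#' @param imageSize c(rows, cols) in pixels.
#' @param pixelSize pixel edge length in micrometres (default 0.758).
#' @param cells list of `list(spec = <ShapeSpec>, center = c(row, col))`.
#' @param particles list of `list(center = c(row, col) | NULL, radius = um,
#'   engulfedBy = cell index | NA)`. An engulfed particle with no center is
#'   placed at its host's soma center.
#' @param backgroundLevel constant background intensity (both channels).
#' @param noiseSd standard deviation of additive Gaussian noise (0 = none).
#' @param cellIntensity,particleIntensity foreground amplitudes.
#' @param allowOverlap allow overlapping cells (truth label = later cell).
#' @param seed integer seed for the noise.
#' @return A list of class `FieldSpec`.
#' @export
fieldSpec <- function(imageSize, pixelSize = 0.758, cells = list(),
                      particles = list(), backgroundLevel = 10, noiseSd = 0,
                      cellIntensity = 15, particleIntensity = 15,
                      allowOverlap = FALSE, seed = 1L) {
  stopifnot(length(imageSize) == 2, all(imageSize >= 8), pixelSize > 0,
            backgroundLevel >= 0, noiseSd >= 0)
  for (cl in cells) {
    stopifnot(inherits(cl$spec, "ShapeSpec"), length(cl$center) == 2)
    if (cl$center[1] < 1 || cl$center[1] > imageSize[1] ||
        cl$center[2] < 1 || cl$center[2] > imageSize[2])
      stop("cell center outside image")
  }
  structure(list(imageSize = as.integer(imageSize), pixelSize = pixelSize,
                 cells = cells, particles = particles,
                 backgroundLevel = backgroundLevel, noiseSd = noiseSd,
                 cellIntensity = cellIntensity,
                 particleIntensity = particleIntensity,
                 allowOverlap = allowOverlap, seed = as.integer(seed)),
            class = "FieldSpec")
}

# paste a patch into an image at center (row, col); returns indices placed
.pasteIndices <- function(patch, center, dims) {
  pc <- attr(patch, "center")
  idx <- which(patch > 0)
  pr <- (idx - 1L) %% nrow(patch) + 1L
  pcl <- (idx - 1L) %/% nrow(patch) + 1L
  r <- pr - pc[1] + round(center[1])
  c <- pcl - pc[2] + round(center[2])
  keep <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2]
  list(img = cbind(r[keep], c[keep]), patch = idx[keep], nInside = sum(keep))
}

#' Render a synthetic field
#'
#' Rasterizes a [fieldSpec()] into a two-channel [Field-class] plus full
#' ground truth: the cell label mask, a cell table and a particle table.
#' Engulfed particles are guaranteed to lie strictly inside their host
#' cell's mask (otherwise rendering fails).
#'
#' @param fs a `FieldSpec`.
#' @return list with `field` (a `Field`), `labels` (integer truth mask),
#'   `cells` (data.frame: cell_id, class_name, center, area_px) and
#'   `particles` (data.frame: particle_id, center, radius_um, area_px,
#'   engulfed_by).
#' @export
renderField <- function(fs) {
  stopifnot(inherits(fs, "FieldSpec"))
  dims <- fs$imageSize
  red <- matrix(fs$backgroundLevel, dims[1], dims[2])
  green <- matrix(fs$backgroundLevel, dims[1], dims[2])
  labels <- matrix(0L, dims[1], dims[2])
  cellRows <- list()
  cellCenters <- list()
  for (k in seq_along(fs$cells)) {
    cl <- fs$cells[[k]]
    p <- renderCell(cl$spec, fs$pixelSize)
    m <- p$mask; attr(m, "center") <- p$center
    placed <- .pasteIndices(m, cl$center, dims)
    if (placed$nInside == 0)
      stop("cell ", k, " falls entirely outside the image")
    if (!fs$allowOverlap && any(labels[placed$img] > 0))
      stop("cell ", k, " overlaps an earlier cell; set allowOverlap = TRUE ",
           "if intended")
    labels[placed$img] <- k
    red[placed$img] <- fs$backgroundLevel +
      fs$cellIntensity * p$intensity[placed$patch]
    cellCenters[[k]] <- round(cl$center)
    cellRows[[k]] <- data.frame(cell_id = k,
                                class_name = cl$spec$className,
                                center_row = round(cl$center[1]),
                                center_col = round(cl$center[2]),
                                area_px = placed$nInside)
  }
  partRows <- list()
  for (j in seq_along(fs$particles)) {
    pt <- fs$particles[[j]]
    host <- if (is.null(pt$engulfedBy)) NA_integer_ else pt$engulfedBy
    center <- pt$center
    if (is.null(center)) {
      if (is.na(host)) stop("free particle ", j, " needs a center")
      center <- cellCenters[[host]]
    }
    rpx <- pt$radius / fs$pixelSize
    h <- ceiling(rpx)
    rs <- max(1, round(center[1]) - h):min(dims[1], round(center[1]) + h)
    cs <- max(1, round(center[2]) - h):min(dims[2], round(center[2]) + h)
    grid <- expand.grid(r = rs, c = cs)
    inside <- (grid$r - center[1])^2 + (grid$c - center[2])^2 <= rpx^2
    px <- cbind(grid$r[inside], grid$c[inside])
    if (nrow(px) == 0) stop("particle ", j, " rasterizes to zero pixels")
    if (!is.na(host)) {
      hostPx <- labels[px] == host
      if (!all(hostPx))
        stop("engulfed particle ", j, " is not strictly inside cell ", host)
    }
    green[px] <- fs$backgroundLevel + fs$particleIntensity
    partRows[[j]] <- data.frame(particle_id = j,
                                center_row = center[1], center_col = center[2],
                                radius_um = pt$radius, area_px = nrow(px),
                                engulfed_by = host)
  }
  if (fs$noiseSd > 0) {
    .withSeed(fs$seed, function() {
      red <<- pmax(red + matrix(rnorm(prod(dims), 0, fs$noiseSd),
                                dims[1], dims[2]), 0)
      green <<- pmax(green + matrix(rnorm(prod(dims), 0, fs$noiseSd),
                                    dims[1], dims[2]), 0)
    })
  }
  list(field = Field(red, green, pixelSize = fs$pixelSize),
       labels = labels,
       cells = if (length(cellRows)) do.call(rbind, cellRows) else
         data.frame(cell_id = integer(), class_name = character(),
                    center_row = numeric(), center_col = numeric(),
                    area_px = integer()),
       particles = if (length(partRows)) do.call(rbind, partRows) else
         data.frame(particle_id = integer(), center_row = numeric(),
                    center_col = numeric(), radius_um = numeric(),
                    area_px = integer(), engulfed_by = integer()))
}

#' Render a synthetic time-lapse
#'
#' Repeats [renderField()] over frames, translating each cell by its
#' per-frame displacement. Engulfed particles move with their host cell
#' (fixed offset from the host center) and their area shrinks by
#' `shrinkRate` per frame (radius scaled by `sqrt(1 - shrinkRate)`); free
#' particles are static.
#'
#' @param fs a `FieldSpec` describing frame 1.
#' @param nFrames number of frames (>= 2).
#' @param motion matrix (nCells x 2) of per-frame (row, col) displacement in
#'   pixels, or a single c(dr, dc) recycled over cells.
#' @param shrinkRate fractional area decrease per frame for engulfed
#'   particles (0 = constant size).
#' @return list with `fields`, `labels`, `cells`, `particles`: one entry
#'   per frame.
#' @export
renderTimelapse <- function(fs, nFrames, motion = c(0, 0), shrinkRate = 0) {
  stopifnot(inherits(fs, "FieldSpec"), nFrames >= 2,
            shrinkRate >= 0, shrinkRate < 1)
  nc <- length(fs$cells)
  if (is.null(dim(motion))) motion <- matrix(motion, nc, 2, byrow = TRUE)
  stopifnot(nrow(motion) == nc)
  # resolve engulfed-particle offsets relative to host centers at frame 1
  offsets <- lapply(fs$particles, function(pt) {
    host <- if (is.null(pt$engulfedBy)) NA_integer_ else pt$engulfedBy
    if (is.na(host)) return(NULL)
    ctr <- if (is.null(pt$center)) fs$cells[[host]]$center else pt$center
    ctr - fs$cells[[host]]$center
  })
  out <- list(fields = vector("list", nFrames), labels = vector("list", nFrames),
              cells = vector("list", nFrames), particles = vector("list", nFrames))
  for (t in seq_len(nFrames)) {
    cells_t <- fs$cells
    for (k in seq_len(nc))
      cells_t[[k]]$center <- fs$cells[[k]]$center + (t - 1) * motion[k, ]
    parts_t <- fs$particles
    for (j in seq_along(parts_t)) {
      host <- parts_t[[j]]$engulfedBy
      if (!is.null(host) && !is.na(host)) {
        parts_t[[j]]$center <- cells_t[[host]]$center + offsets[[j]]
        parts_t[[j]]$radius <- parts_t[[j]]$radius *
          sqrt((1 - shrinkRate)^(t - 1))
      } else if (is.null(parts_t[[j]]$center)) {
        stop("free particle ", j, " needs a center")
      }
    }
    fst <- fs
    fst$cells <- cells_t
    fst$particles <- parts_t
    fst$seed <- fs$seed + (t - 1L) * 1000L
    class(fst) <- "FieldSpec"
    rf <- tryCatch(renderField(fst), error = function(e)
      stop("frame ", t, ": ", conditionMessage(e)))
    rf$field@time <- t
    out$fields[[t]] <- rf$field
    out$labels[[t]] <- rf$labels
    out$cells[[t]] <- if (nrow(rf$cells))
      cbind(frame = t, rf$cells) else cbind(frame = integer(0), rf$cells)
    out$particles[[t]] <- if (nrow(rf$particles))
      cbind(frame = t, rf$particles) else
      cbind(frame = integer(0), rf$particles)
  }
  out
}

#' Lay out non-overlapping archetype cells on a field
#'
#' Convenience builder: places `n` cells (cycling through the given
#' classes, with size jitter) on a jittered grid sized so that cells do not
#' overlap, and optionally adds free and engulfed debris particles.
#'
#' @param n number of cells.
#' @param classes morphology classes to cycle through.
#' @param seed integer seed.
#' @param pixelSize micrometres per pixel.
#' @param noiseSd noise level passed to [fieldSpec()].
#' @param nFreeParticles,nEngulfed number of free / engulfed particles.
#' @param particleRadius particle radius (um).
#' @param jitter relative size jitter passed to [archetypeSpec()].
#' @return A `FieldSpec`.
#' @export
demoFieldSpec <- function(n = 10, classes = morphologyClasses(), seed = 1L,
                          pixelSize = 0.758, noiseSd = 0,
                          nFreeParticles = 0, nEngulfed = 0,
                          particleRadius = 2.5, jitter = 0.08) {
  specs <- lapply(seq_len(n), function(k)
    archetypeSpec(classes[((k - 1) %% length(classes)) + 1],
                  seed = seed * 1000L + k, jitter = jitter))
  # per-cell patch extent in px decides the grid pitch
  ext <- vapply(specs, function(s) {
    p <- renderCell(s, pixelSize); nrow(p$mask)
  }, numeric(1))
  pitch <- max(ext) + 6
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  dims <- c(nrows, ncols) * pitch + 2
  # free particles live in a cell-free margin band on the right
  if (nFreeParticles > 0) dims[2] <- dims[2] + round(pitch / 2)
  cells <- .withSeed(seed, function() lapply(seq_len(n), function(k) {
    gr <- (k - 1) %/% ncols; gc <- (k - 1) %% ncols
    jit <- runif(2, -2, 2)
    list(spec = specs[[k]],
         center = round(c(gr + 0.5, gc + 0.5) * pitch + 1 + jit))
  }))
  particles <- list()
  if (nEngulfed > 0) {
    hosts <- rep(seq_len(n), length.out = nEngulfed)
    for (h in hosts)
      particles[[length(particles) + 1L]] <-
        list(center = NULL, radius = particleRadius, engulfedBy = h)
  }
  if (nFreeParticles > 0) {
    rpx <- ceiling(particleRadius / pixelSize) + 2
    free <- .withSeed(seed + 77L, function()
      lapply(seq_len(nFreeParticles), function(j) {
        list(center = c(runif(1, rpx + 1, dims[1] - rpx - 1),
                        runif(1, ncols * pitch + rpx + 2, dims[2] - rpx - 1)),
             radius = particleRadius, engulfedBy = NA_integer_)
      }))
    particles <- c(particles, free)
  }
  fieldSpec(dims, pixelSize = pixelSize, cells = cells,
            particles = particles, noiseSd = noiseSd, seed = seed)
}
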