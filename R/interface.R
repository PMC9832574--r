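# Reporting across treatment groups and end-to-end orchestration.

#' Morphology composition table across groups
#'
#' Tabulates assigned classes per treatment group: counts and per-group
#' percentages (columns: the seven classes plus "unassigned"). Empty
#' groups are omitted with a warning.
#'
#' @param assignedClass character vector of assigned classes.
#' @param group parallel vector of group labels.
#' @return list of class `CompositionTable` with `counts` and `percent`
#'   matrices (rows = groups).
#' @export
composeTable <- function(assignedClass, group) {
  stopifnot(length(assignedClass) == length(group))
  lv <- c(morphologyClasses(), "unassigned")
  extra <- setdiff(unique(assignedClass), lv)
  lv <- c(setdiff(lv, "unassigned"), extra, "unassigned")
  groups <- unique(group)
  empty <- vapply(groups, function(g) sum(group == g) == 0, logical(1))
  if (any(empty)) {
    warning("empty group(s) omitted: ", paste(groups[empty], collapse = ", "))
    groups <- groups[!empty]
  }
  counts <- t(vapply(groups, function(g)
    table(factor(assignedClass[group == g], levels = lv)),
    numeric(length(lv))))
  rownames(counts) <- groups
  colnames(counts) <- lv
  pct <- sweep(counts, 1, rowSums(counts), "/") * 100
  structure(list(counts = counts, percent = pct),
            class = "CompositionTable")
}

#' @export
print.CompositionTable <- function(x, ...) {
  cat("Morphology composition (counts):\n")
  print(x$counts)
  cat("\nPer-group percent:\n")
  print(round(x$percent, 1))
  invisible(x)
}

#' Chi-squared comparison of two group compositions
#'
#' Pearson chi-squared test on the 2 x C table of class counts for two
#' groups. Classes in which both groups have zero cells carry no
#' information and would give zero expected counts; they are pooled out
#' of the table (noted in the result). Degrees of freedom: C - 1 for the
#' C retained classes.
#'
#' @param composition a [composeTable()] result (or a counts matrix).
#' @param groupA,groupB row names of the two groups to compare.
#' @return list: `statistic`, `df`, `p.value`, `pooled` (dropped
#'   classes).
#' @export
compareCompositions <- function(composition, groupA, groupB) {
  counts <- if (inherits(composition, "CompositionTable"))
    composition$counts else composition
  if (!all(c(groupA, groupB) %in% rownames(counts)))
    stop("both groups must be rows of the composition table")
  O <- counts[c(groupA, groupB), , drop = FALSE]
  zero <- colSums(O) == 0
  pooled <- colnames(O)[zero]
  O <- O[, !zero, drop = FALSE]
  C <- ncol(O)
  if (C < 2) stop("fewer than two informative classes: df would be 0")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  stat <- sum((O - E)^2 / E)
  df <- C - 1
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       pooled = pooled)
}

#' Pairwise composition tests against a control group
#'
#' Runs [compareCompositions()] of every non-control group against the
#' control and adjusts the p-values with the Benjamini-Hochberg
#' procedure.
#'
#' @param composition a [composeTable()] result.
#' @param control control group row name.
#' @return data.frame: group, statistic, df, p.value, adj.p.value.
#' @export
compareAllCompositions <- function(composition, control) {
  counts <- composition$counts
  others <- setdiff(rownames(counts), control)
  res <- do.call(rbind, lapply(others, function(g) {
    r <- tryCatch(compareCompositions(composition, control, g),
                  error = function(e) {
                    warning("comparison ", control, " vs ", g, ": ",
                            conditionMessage(e))
                    list(statistic = NA_real_, df = NA_integer_,
                         p.value = NA_real_)
                  })
    data.frame(group = g, statistic = r$statistic, df = r$df,
               p.value = r$p.value)
  }))
  res$adj.p.value <- stats::p.adjust(res$p.value, method = "BH")
  res
}

# default pipeline configuration; user values are merged over these
.defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    pixelSize = NULL,  # required: every stage needs physical units
    outDir = NULL,
    simulate = list(nCellsPerGroup = 14, groups = c("control", "treated"),
                    noiseSd = 1, nFrames = 3, motion = c(2, 0),
                    shrinkRate = 0.2, nFreeParticles = 2, nEngulfed = 3,
                    analysisFrame = 1),
    segmentation = list(minCellSize = 200, maxSkeletonLength = 450,
                        thresholdFactor = 1.5, diffusionIterations = 5,
                        diffusionConductance = 5),
    # demo fields hold a few cells per class, so the pipeline default
    # cluster floor is smaller than the clusterer's own default of 10
    classify = list(minClusterSize = 4, annotationFraction = 0.6),
    # relative particle threshold: synthetic demo fields carry little
    # debris, too little for the histogram-splitting methods
    phago = list(particleMethod = "relative", minShrink = 0.1,
                 coMoveTol = 3)
  )
}

.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]))
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates simulate -> segment -> measure -> classify -> phago ->
#' report on generated fields, logging each stage, and writes every table
#' as CSV under `config$outDir` (if set). All randomness derives from
#' `config$seed`, so a rerun with the same configuration produces
#' byte-identical CSV outputs.
#'
#' @param config nested configuration list (or path to a JSON file); see
#'   the package vignette. `pixelSize` is required.
#' @param quiet suppress progress messages.
#' @return list with `features`, `assignments`, `composition`,
#'   `comparisons`, `phago` (per group), `masks`, and `paths` of written
#'   files.
#' @export
runPipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  cfg <- .mergeConfig(.defaultPipelineConfig(), config)
  if (is.null(cfg$pixelSize) || !is.finite(cfg$pixelSize) ||
      cfg$pixelSize <= 0)
    stop("config: pixelSize is required and must be positive")
  say <- function(...) if (!quiet) message("[pipeline] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  seed <- as.integer(cfg$seed)
  groups <- cfg$simulate$groups
  say("simulate: ", length(groups), " group(s), ",
      cfg$simulate$nCellsPerGroup, " cells each, ",
      cfg$simulate$nFrames, " frame(s), seed ", seed)
  sims <- stage("simulate", lapply(seq_along(groups), function(gi) {
    fs <- demoFieldSpec(n = cfg$simulate$nCellsPerGroup,
                        seed = seed + 131L * gi,
                        pixelSize = cfg$pixelSize,
                        noiseSd = cfg$simulate$noiseSd,
                        nFreeParticles = cfg$simulate$nFreeParticles,
                        nEngulfed = cfg$simulate$nEngulfed)
    renderTimelapse(fs, nFrames = cfg$simulate$nFrames,
                    motion = cfg$simulate$motion,
                    shrinkRate = cfg$simulate$shrinkRate)
  }))
  names(sims) <- groups
  segCfg <- segmentationConfig(
    minCellSize = cfg$segmentation$minCellSize,
    maxSkeletonLength = cfg$segmentation$maxSkeletonLength,
    thresholdFactor = cfg$segmentation$thresholdFactor,
    diffusionIterations = cfg$segmentation$diffusionIterations,
    diffusionConductance = cfg$segmentation$diffusionConductance,
    pixelSize = cfg$pixelSize)
  say("segment: relative threshold ", segCfg$thresholdFactor,
      ", min cell size ", segCfg$minCellSize, " um2, max skeleton ",
      segCfg$maxSkeletonLength, " um")
  masks <- stage("segment", lapply(sims, function(sim) {
    trackMasks(lapply(sim$fields, segmentFrame, config = segCfg))
  }))
  frame <- cfg$simulate$analysisFrame
  say("measure: frame ", frame)
  features <- stage("measure", do.call(rbind, lapply(groups, function(g) {
    f <- sims[[g]]$fields[[frame]]
    rec <- measureCells(masks[[g]][[frame]], redChannel(f), cfg$pixelSize,
                        frame = frame)
    rec <- deriveFeatures(rec)
    rec <- filterIncomplete(rec)
    rec$group <- rep(g, nrow(rec))
    # ground-truth class of the best-overlapping truth cell
    truth <- sims[[g]]$labels[[frame]]
    rec$true_class <- vapply(rec$cell_id, function(id) {
      ov <- table(truth[masks[[g]][[frame]] == id & truth > 0])
      if (!length(ov)) NA_character_
      else sims[[g]]$cells[[frame]]$class_name[
        as.integer(names(ov)[which.max(ov)])]
    }, character(1))
    rec
  })))
  say("classify: annotate ", round(100 * cfg$classify$annotationFraction),
      "% of cells with ground truth, cluster and vote")
  cls <- stage("classify", {
    features$annotation <- NA_character_
    .withSeed(seed + 997L, function() {
      # stratified annotation: at least two cells per class when available
      for (cls in unique(stats::na.omit(features$true_class))) {
        idx <- which(features$true_class == cls)
        nAnn <- min(length(idx),
                    max(2, round(cfg$classify$annotationFraction *
                                 length(idx))))
        pick <- sort(sample(idx, nAnn))
        features$annotation[pick] <<- features$true_class[pick]
      }
    })
    assignMorphologies(features,
                       minClusterSize = cfg$classify$minClusterSize,
                       seed = seed)
  })
  assignments <- cls$assignments
  assignments$group <- features$group
  say("phago: particle threshold ", cfg$phago$particleMethod,
      ", min shrink ", cfg$phago$minShrink)
  phago <- stage("phago", lapply(groups, function(g)
    phagoAnalysis(sims[[g]]$fields, masks[[g]],
                  particleMethod = cfg$phago$particleMethod,
                  minShrink = cfg$phago$minShrink,
                  coMoveTol = cfg$phago$coMoveTol)))
  names(phago) <- groups
  say("report: composition and pairwise comparisons")
  composition <- stage("report",
                       composeTable(assignments$assigned_class,
                                    assignments$group))
  comparisons <- if (length(groups) > 1)
    compareAllCompositions(composition, groups[1]) else NULL
  paths <- character(0)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    wr <- function(df, name) {
      p <- file.path(cfg$outDir, name)
      write.csv(df, p, row.names = FALSE)
      p
    }
    paths <- c(
      features = wr(features, "features.csv"),
      assignments = wr(assignments, "assignments.csv"),
      composition = wr(cbind(group = rownames(composition$counts),
                             as.data.frame(composition$counts)),
                       "composition.csv"),
      phago = wr(do.call(rbind, lapply(groups, function(g)
        cbind(group = g, phago[[g]]$report))), "phago_report.csv"))
    if (!is.null(comparisons))
      paths <- c(paths, comparisons = wr(comparisons, "comparisons.csv"))
    for (g in groups) {
      mp <- file.path(cfg$outDir, sprintf("mask_%s_frame%d.tif", g, frame))
      writeLabelMaskTiff(masks[[g]][[frame]], mp)
      paths <- c(paths, stats::setNames(mp, paste0("mask_", g)))
    }
  }
  list(features = features, assignments = assignments,
       composition = composition, comparisons = comparisons,
       phago = phago, masks = masks, config = cfg, paths = paths)
}
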