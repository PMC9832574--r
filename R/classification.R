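# Morphology classification: supervised 2-D metric-learning embedding of
# annotated cells (z-scored features, PCA pre-whitening, Fisher linear
# discriminant axes), projection of unannotated cells through the learned
# linear map, density clustering of the embedding with a noise class, and
# per-cluster majority voting of the annotated members; evaluated by
# stratified k-fold cross-validation.

#' Default classifier feature columns
#'
#' All base shape features plus the ten derived ratios; intensity
#' summaries and centroids are excluded by default (they reflect
#' acquisition settings and position, not morphology).
#' @return character vector.
#' @export
classifierFeatureNames <- function() {
  c(baseShapeFeatureNames(), derivedFeatureNames())
}

#' Fit the supervised morphology embedding
#'
#' Learns a linear map from the feature space to two dimensions that
#' separates the annotated morphology classes while preserving the
#' overall structure of the data: features are z-scored on the training
#' cells, reduced by PCA (dropping numerically null directions, which
#' absorbs the exact collinearity between base and derived features), and
#' projected into the leading discriminant subspace of the regularized
#' criterion W^-1 B + alpha T, where B, W and T are the between-class,
#' within-class and total scatter matrices. With informative labels this
#' is Fisher discriminant analysis; as the labels carry less information
#' the criterion degrades gracefully towards a principal-component
#' projection instead of collapsing. Because any one 2-D plane of the
#' discriminant subspace can superimpose a pair of classes, the final
#' two axes are the plane maximizing the smallest pairwise projected
#' class-mean separation (a deterministic seeded search over rotations).
#' The training embedding and annotations are stored so new cells can
#' later be clustered together with the training cells.
#'
#' @param records cell record table with an `annotation` column naming the
#'   morphology class of each training cell.
#' @param featureColumns feature columns to use (default
#'   [classifierFeatureNames()], intersected with available columns).
#' @param minClusterSize minimum density-cluster size stored with the
#'   model (default 10).
#' @param na how to treat rows with missing feature values: "impute"
#'   (column median; the default, since whole morphology classes can have
#'   a structurally undefined ratio, e.g. Thickness for cells whose
#'   skeleton degenerates to a point) or "drop".
#' @param alpha weight of the structure-preservation (total variance)
#'   term relative to the between-class term (default 0.05).
#' @param seed integer seed recorded with the model (the fit itself is
#'   deterministic; the seed seeds downstream clustering reproducibly).
#' @return A [MorphologyModel-class].
#' @export
fitEmbedding <- function(records, featureColumns = NULL,
                         minClusterSize = 10, na = c("impute", "drop"),
                         alpha = 0.05, seed = 1L) {
  na <- match.arg(na)
  if (is.null(featureColumns))
    featureColumns <- intersect(classifierFeatureNames(), names(records))
  missingCols <- setdiff(featureColumns, names(records))
  if (length(missingCols))
    stop("missing feature column(s): ", paste(missingCols, collapse = ", "))
  ann <- records$annotation
  keep <- !is.na(ann) & ann != ""
  records <- records[keep, , drop = FALSE]
  ann <- ann[keep]
  X <- as.matrix(records[, featureColumns, drop = FALSE])
  if (na == "drop") {
    ok <- apply(is.finite(X), 1, all)
    X <- X[ok, , drop = FALSE]; ann <- ann[ok]
  }
  # imputation values are stored with the model so new cells with the
  # same structurally missing ratios are placed consistently
  imputeVals <- apply(X, 2, function(x) {
    v <- stats::median(x[is.finite(x)])
    if (is.finite(v)) v else 0
  })
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- imputeVals[j]
  }
  if (length(unique(ann)) < 2)
    stop("at least two annotated classes are required")
  tab <- table(ann)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("class(es) with fewer than 2 members: ",
         paste(small, collapse = ", "))
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  use <- scl > 0
  if (!any(use)) stop("all features are constant")
  featureColumns <- featureColumns[use]
  X <- X[, use, drop = FALSE]
  ctr <- ctr[use]; scl <- scl[use]; imputeVals <- imputeVals[use]
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  keepPc <- pc$sdev > max(pc$sdev) * 1e-6
  rot <- pc$rotation[, keepPc, drop = FALSE]
  Zp <- Z %*% rot
  # scatter matrices in the reduced space
  g <- factor(ann)
  mu <- colMeans(Zp)
  p <- ncol(Zp)
  B <- matrix(0, p, p); W <- matrix(0, p, p)
  for (lv in levels(g)) {
    Zi <- Zp[g == lv, , drop = FALSE]
    mi <- colMeans(Zi)
    B <- B + nrow(Zi) * tcrossprod(mi - mu)
    W <- W + crossprod(sweep(Zi, 2, mi))
  }
  B <- B / nrow(Zp); W <- W / nrow(Zp)
  Tm <- B + W
  ridge <- diag(1e-6 * mean(diag(W)) + 1e-12, p)
  # discriminant ratio term plus a structure (total variance) term: the
  # first dominates when labels are informative (its eigenvalues are
  # scale-free between/within ratios, huge for separated classes), the
  # second takes over as label information vanishes
  M <- solve(W + ridge, B) + alpha * Tm
  e <- eigen(M)
  ord <- order(-Re(e$values))
  m <- min(max(2, nlevels(g) - 1), p, 6)
  V <- Re(e$vectors[, ord[seq_len(m)], drop = FALSE])
  if (ncol(V) < 2) V <- cbind(V, 0)
  Zd <- Zp %*% V
  # normalize the discriminant axes to unit pooled within-class sd so
  # distances are commensurable across axes
  wsd <- vapply(seq_len(ncol(Zd)), function(j)
    sqrt(mean(unlist(tapply(Zd[, j], g, function(x) (x - mean(x))^2)))),
    numeric(1))
  wsd[!is.finite(wsd) | wsd <= 0] <- 1
  V <- sweep(V, 2, wsd, "/")
  Zd <- sweep(Zd, 2, wsd, "/")
  # any single 2-D plane of the discriminant space can superimpose a
  # pair of classes; pick the plane that maximizes the smallest pairwise
  # projected class-mean separation (deterministic seeded search)
  mu_c <- t(vapply(levels(g), function(lv)
    colMeans(Zd[g == lv, , drop = FALSE]), numeric(ncol(Zd))))
  minSep <- function(basis) {
    pm <- mu_c %*% basis
    min(stats::dist(pm))
  }
  basis <- diag(ncol(Zd))[, 1:2, drop = FALSE]
  if (ncol(Zd) > 2 && nlevels(g) > 2) {
    best <- minSep(basis)
    cands <- .withSeed(1803L, function()
      lapply(seq_len(500), function(i)
        qr.Q(qr(matrix(rnorm(ncol(Zd) * 2), ncol(Zd), 2)))))
    for (cb in cands) {
      s <- minSep(cb)
      if (s > best) { best <- s; basis <- cb }
    }
  }
  proj <- rot %*% V %*% basis
  colnames(proj) <- c("dim1", "dim2")
  emb <- Z %*% proj
  # fix axis scale and sign for reproducibility across equivalent fits
  sds <- apply(emb, 2, stats::sd)
  sds[sds == 0] <- 1
  proj <- sweep(proj, 2, sds, "/")
  for (j in 1:2) if (sum(proj[, j]^3) < 0) proj[, j] <- -proj[, j]
  emb <- Z %*% proj
  new("MorphologyModel", featureColumns = featureColumns,
      center = ctr, scale = scl, impute = imputeVals, projection = proj,
      classLevels = sort(unique(ann)), trainingEmbedding = emb,
      trainingClasses = as.character(ann),
      minClusterSize = as.integer(minClusterSize), seed = as.integer(seed))
}

#' Project cells into a fitted morphology embedding
#'
#' Applies the model's learned transform (z-score with the training
#' parameters, then the linear projection) to new cell records. Training
#' cells are not re-fitted; projecting them reproduces their training
#' coordinates exactly.
#'
#' @param model a [MorphologyModel-class].
#' @param records cell record table carrying the model's feature columns.
#' @return numeric matrix (n x 2) of embedding coordinates.
#' @export
projectCells <- function(model, records) {
  missingCols <- setdiff(model@featureColumns, names(records))
  if (length(missingCols))
    stop("missing feature column(s): ", paste(missingCols, collapse = ", "))
  if (!nrow(records))
    return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("dim1", "dim2"))))
  X <- as.matrix(records[, model@featureColumns, drop = FALSE])
  for (j in seq_len(ncol(X))) {
    bad <- !is.finite(X[, j])
    if (any(bad)) X[bad, j] <- model@impute[j]
  }
  Z <- sweep(sweep(X, 2, model@center), 2, model@scale, "/")
  Z %*% model@projection
}

#' Density clustering of embedding coordinates
#'
#' Hierarchical density clustering with a noise class, in the
#' mutual-reachability formulation: each point's core distance is its
#' distance to the (minPts-1)-th neighbour, pairwise distances are
#' replaced by `max(d, core_i, core_j)`, and a minimum spanning tree of
#' the result is cut at edges longer than `cutFactor` times the median
#' tree edge. The surviving components of at least `minClusterSize`
#' points are the clusters; everything else is noise (cluster 0). The
#' relative cut makes the clustering scale-free: dense regions stay
#' together whatever the absolute scale of the embedding, and bridges
#' between separated groups are always long relative to within-group
#' edges. Alternatively a fixed radius `eps` can be supplied, in which
#' case tree edges longer than `eps` are cut instead.
#'
#' @param coords numeric matrix (n x 2).
#' @param minClusterSize minimum cluster size (default 10); fewer input
#'   points than this yields all noise.
#' @param eps optional fixed cut radius overriding the relative rule.
#' @param minPts core-distance neighbour count (default
#'   `min(minClusterSize, n - 1)`, at least 3).
#' @param cutFactor relative cut level (default 3).
#' @return integer vector of cluster ids, 0 = noise.
#' @export
clusterEmbedding <- function(coords, minClusterSize = 10, eps = NULL,
                             minPts = NULL, cutFactor = 3) {
  n <- nrow(coords)
  if (n == 0) return(integer(0))
  if (n < minClusterSize) return(integer(n))
  if (is.null(minPts)) minPts <- max(3, min(minClusterSize, n - 1))
  d <- as.matrix(stats::dist(coords))
  core <- apply(d, 1, function(x) sort(x)[minPts])  # self is position 1
  mr <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
  g <- igraph::graph_from_adjacency_matrix(mr, mode = "undirected",
                                           weighted = TRUE)
  mt <- igraph::mst(g)
  w <- igraph::E(mt)$weight
  cut <- if (is.null(eps)) cutFactor * stats::median(w) else eps
  mt <- igraph::delete_edges(mt, igraph::E(mt)[w > cut])
  cl <- igraph::components(mt)$membership
  sizes <- tabulate(cl)
  cl[sizes[cl] < minClusterSize] <- 0L
  # relabel 1..K in order of first occurrence, for reproducibility
  labs <- unique(cl[cl > 0])
  cl[cl > 0] <- match(cl[cl > 0], labs)
  as.integer(cl)
}

#' Majority-vote class labels for clusters
#'
#' Each cluster is labelled with the most frequent annotation among its
#' annotated members and every member inherits that label. Clusters with
#' no annotated member, clusters whose top annotations tie, and noise
#' points are labelled "unassigned" (the conservative choice: no
#' arbitrary tie-breaking).
#'
#' @param clusterIds integer vector from [clusterEmbedding()] (0 = noise).
#' @param annotations character vector parallel to `clusterIds`; NA for
#'   unannotated cells. At least one annotation must be present.
#' @return character vector of assigned classes ("unassigned" allowed).
#' @export
voteClusters <- function(clusterIds, annotations) {
  stopifnot(length(clusterIds) == length(annotations))
  if (all(is.na(annotations)))
    stop("at least one annotated cell is required")
  out <- rep("unassigned", length(clusterIds))
  for (k in setdiff(unique(clusterIds), 0L)) {
    members <- clusterIds == k
    ann <- annotations[members]
    ann <- ann[!is.na(ann)]
    if (!length(ann)) next
    tab <- sort(table(ann), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) next  # tie -> unassigned
    out[members] <- names(tab)[1]
  }
  out
}

#' Assign a morphology class to every cell
#'
#' The full classification pipeline: fit the supervised embedding on the
#' annotated cells, place all cells in the plane (annotated cells keep
#' their training coordinates; unannotated cells are projected), cluster
#' the combined embedding and propagate cluster votes. Every input cell
#' receives exactly one assignment row.
#'
#' @param records cell record table with an `annotation` column (NA =
#'   unannotated).
#' @param featureColumns,minClusterSize,seed passed to [fitEmbedding()] /
#'   [clusterEmbedding()].
#' @return list with `assignments` (data.frame: cell_id, frame_index,
#'   dim1, dim2, cluster_id, assigned_class, was_annotated) and `model`.
#' @export
assignMorphologies <- function(records, featureColumns = NULL,
                               minClusterSize = 10, seed = 1L) {
  model <- fitEmbedding(records, featureColumns = featureColumns,
                        minClusterSize = minClusterSize, seed = seed)
  res <- .assignWithModel(model, records)
  list(assignments = res, model = model)
}

# embed all records (training rows via the stored coordinates is
# equivalent to projecting them: the map is linear), cluster, vote
.assignWithModel <- function(model, records) {
  coords <- projectCells(model, records)
  ann <- if ("annotation" %in% names(records)) records$annotation
         else rep(NA_character_, nrow(records))
  ann[!is.na(ann) & ann == ""] <- NA_character_
  cl <- clusterEmbedding(coords, minClusterSize = model@minClusterSize)
  cls <- voteClusters(cl, ann)
  data.frame(cell_id = if ("cell_id" %in% names(records)) records$cell_id
             else seq_len(nrow(records)),
             frame_index = if ("frame_index" %in% names(records))
               records$frame_index else 1L,
             dim1 = coords[, 1], dim2 = coords[, 2],
             cluster_id = cl, assigned_class = cls,
             was_annotated = !is.na(ann))
}

#' Predict classes for new cells with a fitted model
#'
#' Projects new records into the model's embedding, clusters them together
#' with the stored training cells and votes with the training annotations;
#' returns assignments for the new records only.
#'
#' @param model a [MorphologyModel-class].
#' @param records unannotated cell record table.
#' @return data.frame of assignments (one row per input record).
#' @export
predictAssignments <- function(model, records) {
  coordsNew <- projectCells(model, records)
  coords <- rbind(model@trainingEmbedding, coordsNew)
  ann <- c(model@trainingClasses, rep(NA_character_, nrow(coordsNew)))
  cl <- clusterEmbedding(coords, minClusterSize = model@minClusterSize)
  cls <- voteClusters(cl, ann)
  idx <- nrow(model@trainingEmbedding) + seq_len(nrow(coordsNew))
  data.frame(cell_id = if ("cell_id" %in% names(records)) records$cell_id
             else seq_len(nrow(records)),
             dim1 = coordsNew[, 1], dim2 = coordsNew[, 2],
             cluster_id = cl[idx], assigned_class = cls[idx],
             was_annotated = FALSE)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Splits the annotated cells into k class-stratified folds; for each
#' fold the embedding is fitted on the training cells only, the held-out
#' cells are projected, clustered together with the training cells and
#' voted on. Accuracy is the fraction of correct predictions among
#' held-out cells that received an assignment; the unassigned fraction is
#' reported separately, and the confusion matrix has true classes as rows
#' and predicted classes plus "unassigned" as columns.
#'
#' @param records annotated cell record table (`annotation` column).
#' @param k number of folds (default 5; must be >= 2 and no class may
#'   have fewer than k members).
#' @param featureColumns,minClusterSize passed through.
#' @param seed integer seed for the fold split.
#' @return list: `accuracy` (over assigned cells), `unassignedFraction`,
#'   `recovery` (correct over all held-out cells, unassigned counting as
#'   not recovered), `confusion`, `predictions` (data.frame with true
#'   class, predicted class, fold).
#' @export
crossValidate <- function(records, k = 5, featureColumns = NULL,
                          minClusterSize = 10, seed = 1L) {
  if (k < 2) stop("k must be >= 2")
  ann <- records$annotation
  keep <- !is.na(ann) & ann != ""
  records <- records[keep, , drop = FALSE]
  ann <- ann[keep]
  tab <- table(ann)
  small <- names(tab)[tab < k]
  if (length(small))
    stop("class(es) with fewer than k members: ",
         paste(small, collapse = ", "))
  folds <- integer(nrow(records))
  .withSeed(seed, function() {
    for (cls in names(tab)) {
      i <- which(ann == cls)
      folds[i] <<- sample(rep_len(seq_len(k), length(i)))
    }
  })
  preds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- records[folds != f, , drop = FALSE]
    test <- records[folds == f, , drop = FALSE]
    model <- fitEmbedding(train, featureColumns = featureColumns,
                          minClusterSize = minClusterSize, seed = seed)
    testU <- test
    testU$annotation <- NULL
    p <- predictAssignments(model, testU)
    preds[[f]] <- data.frame(fold = f, true = test$annotation,
                             predicted = p$assigned_class)
  }
  preds <- do.call(rbind, preds)
  assigned <- preds$predicted != "unassigned"
  accuracy <- if (any(assigned))
    mean(preds$true[assigned] == preds$predicted[assigned]) else NA_real_
  classes <- sort(unique(preds$true))
  confusion <- table(factor(preds$true, levels = classes),
                     factor(preds$predicted,
                            levels = c(classes, "unassigned")))
  list(accuracy = accuracy,
       unassignedFraction = mean(!assigned),
       # end-to-end recovery: correct / total held-out (an unassigned
       # cell counts as not recovered)
       recovery = mean(assigned & preds$true == preds$predicted),
       confusion = confusion, predictions = preds)
}

#' Synthetic seven-class feature table
#'
#' Builds a feature table that emulates the per-class feature
#' distributions of the seven archetypes without rendering every cell:
#' one reference cell per class is rendered and measured, and cells are
#' then sampled log-normally around the class centroids. The `separation`
#' parameter scales the between-class differences (1 = archetype
#' distances, 0 = all classes collapse onto the grand mean) while the
#' within-class scatter stays fixed, which makes classifier difficulty
#' tunable. Derived features are recomputed from the sampled base
#' features with [deriveFeatures()], so the derived columns stay exact
#' functions of the base columns.
#'
#' @param nPerClass cells per class (default 50).
#' @param separation between-class separation scale (default 1).
#' @param seed integer seed.
#' @param pixelSize micrometres per pixel for the reference renders.
#' @return data.frame with `cell_id`, `annotation` and the classifier
#'   feature columns.
#' @export
syntheticFeatureTable <- function(nPerClass = 50, separation = 1,
                                  seed = 1L, pixelSize = 0.758) {
  classes <- morphologyClasses()
  cents <- lapply(seq_along(classes), function(i) {
    p <- renderCell(archetypeSpec(classes[i], seed = 101L + i), pixelSize)
    rec <- measureCells(p$mask, p$intensity, pixelSize)
    unlist(rec[1, baseShapeFeatureNames()])
  })
  cents <- do.call(rbind, cents)
  rownames(cents) <- classes
  eps <- 0.5
  L <- log(cents + eps)
  grand <- colMeans(L)
  Lsep <- sweep(sweep(L, 2, grand, "-") * separation, 2, grand, "+")
  sdBetween <- apply(L, 2, stats::sd)
  sigma <- pmax(0.10 * sdBetween, 0.05)
  .withSeed(seed, function() {
    rows <- list()
    for (i in seq_along(classes)) {
      E <- matrix(rnorm(nPerClass * ncol(L), 0, 1), nPerClass) %*%
        diag(sigma, ncol(L))
      # shared size factor correlates areas and lengths within a cell
      size <- rnorm(nPerClass, 0, 0.04)
      E <- E + outer(size, ifelse(grepl("Area", colnames(L)), 2, 1))
      Xi <- exp(sweep(E, 2, Lsep[i, ], "+")) - eps
      Xi <- pmax(Xi, 0)
      df <- as.data.frame(Xi)
      names(df) <- colnames(L)
      df$SkeletonNumBranchPoints <- round(df$SkeletonNumBranchPoints)
      df$annotation <- classes[i]
      rows[[i]] <- df
    }
    out <- do.call(rbind, rows)
    out <- cbind(cell_id = seq_len(nrow(out)), out, PixelSize = pixelSize)
    deriveFeatures(out)
  })
}
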