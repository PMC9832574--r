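#' @import methods
#' @importFrom stats median quantile sd setNames complete.cases p.adjust pchisq runif rnorm
#' @importFrom utils head read.csv write.csv
NULL

#' Two-channel fluorescence field
#'
#' Container for one acquisition: a red channel carrying the cytoplasmic
#' reporter expressed by microglia and a green channel carrying the
#' nucleic-acid stain that marks cell debris. Images are numeric matrices
#' (rows x columns, row 1 at the top); the physical pixel size is stored in
#' micrometres.
#'
#' @slot red numeric matrix, reporter (cell) channel.
#' @slot green numeric matrix, debris (particle) channel, same dimensions.
#' @slot pixelSize numeric(1), pixel edge length in micrometres.
#' @slot time numeric(1), frame index within a time-lapse (1-based).
#'
#' @examples
#' f <- Field(matrix(10, 64, 64), matrix(2, 64, 64), pixelSize = 0.758)
#' dim(redChannel(f))
#' @export
setClass("Field",
  representation(red = "matrix", green = "matrix",
                 pixelSize = "numeric", time = "numeric"),
  prototype(pixelSize = 0.758, time = 1)
)

setValidity("Field", function(object) {
  msg <- character()
  if (!all(dim(object@red) == dim(object@green)))
    msg <- c(msg, "red and green channels must share dimensions")
  if (length(object@pixelSize) != 1 || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (any(!is.finite(object@red)) || any(!is.finite(object@green)))
    msg <- c(msg, "channel images must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a Field
#'
#' @param red numeric matrix, reporter channel.
#' @param green numeric matrix, particle channel (defaults to zeros).
#' @param pixelSize pixel edge length in micrometres (default 0.758, the
#'   acquisition setting the pipeline was designed around).
#' @param time frame index.
#' @return A [Field-class] object.
#' @export
Field <- function(red, green = NULL, pixelSize = 0.758, time = 1) {
  if (is.null(green)) green <- array(0, dim(red))
  new("Field", red = red, green = green, pixelSize = pixelSize, time = time)
}

#' Fitted morphology classification model
#'
#' Holds everything needed to place new cells into the learned
#' two-dimensional morphology space: the feature columns used, per-feature
#' centring/scaling parameters estimated on the training cells, the linear
#' discriminant projection to 2-D, the training embedding and annotations
#' (kept so that unannotated cells can be clustered together with the
#' training cells and inherit their votes), and the clustering parameters.
#'
#' @slot featureColumns character, feature columns entering the embedding.
#' @slot center,scale numeric, per-feature z-score parameters.
#' @slot impute numeric, per-feature values substituted for missing
#'   entries (training-column medians).
#' @slot projection numeric matrix (length(featureColumns) x 2).
#' @slot classLevels character, morphology class names seen at fit time.
#' @slot trainingEmbedding numeric matrix (n x 2) of training coordinates.
#' @slot trainingClasses character, training annotations (parallel rows).
#' @slot minClusterSize integer(1), minimum density-cluster size.
#' @slot seed integer(1), seed recorded at fit time.
#' @export
setClass("MorphologyModel",
  representation(featureColumns = "character", center = "numeric",
                 scale = "numeric", impute = "numeric",
                 projection = "matrix",
                 classLevels = "character", trainingEmbedding = "matrix",
                 trainingClasses = "character", minClusterSize = "integer",
                 seed = "integer")
)

setValidity("MorphologyModel", function(object) {
  msg <- character()
  p <- length(object@featureColumns)
  if (length(object@center) != p || length(object@scale) != p ||
      length(object@impute) != p)
    msg <- c(msg, "center/scale/impute must match featureColumns")
  if (!all(dim(object@projection) == c(p, 2)))
    msg <- c(msg, "projection must be (n features) x 2")
  if (nrow(object@trainingEmbedding) != length(object@trainingClasses))
    msg <- c(msg, "training embedding and classes must have equal rows")
  if (length(msg)) msg else TRUE
})

#' @describeIn Field-class reporter (red) channel matrix.
#' @param x,object a `Field`.
#' @export
setGeneric("redChannel", function(x) standardGeneric("redChannel"))
#' @describeIn Field-class particle (green) channel matrix.
#' @export
setGeneric("greenChannel", function(x) standardGeneric("greenChannel"))
#' @describeIn Field-class pixel size in micrometres.
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname Field-class
#' @export
setMethod("redChannel", "Field", function(x) x@red)
#' @rdname Field-class
#' @export
setMethod("greenChannel", "Field", function(x) x@green)
#' @rdname Field-class
#' @export
setMethod("pixelSize", "Field", function(x) x@pixelSize)

#' @rdname Field-class
#' @export
setMethod("dim", "Field", function(x) dim(x@red))

setMethod("show", "Field", function(object) {
  d <- dim(object@red)
  cat(sprintf("Field: %d x %d px (%.3f um/px), frame %g\n",
              d[1], d[2], object@pixelSize, object@time))
  cat(sprintf("  red   [%.3g, %.3g]\n", min(object@red), max(object@red)))
  cat(sprintf("  green [%.3g, %.3g]\n", min(object@green), max(object@green)))
})

setMethod("show", "MorphologyModel", function(object) {
  cat(sprintf(
    "MorphologyModel: %d features -> 2-D, %d training cells, %d classes\n",
    length(object@featureColumns), nrow(object@trainingEmbedding),
    length(object@classLevels)))
  cat("  classes:", paste(object@classLevels, collapse = ", "), "\n")
})

#' The seven microglia morphology classes
#'
#' Class names used throughout the package, in canonical order: the four
#' base morphologies (round, fried egg, hypertrophic, bipolar) and the
#' enlarged "inflamed" variants of the first three.
#' @return character vector of length 7.
#' @export
morphologyClasses <- function() {
  c("round", "inflamed_ameboid", "fried_egg", "inflamed_fried_egg",
    "hypertrophic", "inflamed_hypertrophic", "bipolar")
}
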