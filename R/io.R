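# File interchange: multi-page TIFF for fields and label masks, JSON for
# field specifications and mask edits, CSV for tables.

#' Write fields to a multi-page TIFF
#'
#' Pages are ordered frame-major, two channels per frame (red then
#' green), as 32-bit float samples.
#'
#' @param fields a [Field-class] or list of fields (a time-lapse).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFieldTiff <- function(fields, path) {
  if (is(fields, "Field")) fields <- list(fields)
  pages <- list()
  for (f in fields) {
    # intensities are stored divided by 2^16 (the writer's float samples
    # live in [0, 1]); the power-of-two scale is exactly reversible
    pages[[length(pages) + 1L]] <- redChannel(f) / 65536
    pages[[length(pages) + 1L]] <- greenChannel(f) / 65536
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}

#' Read fields from a multi-page TIFF written by [writeFieldTiff()]
#'
#' @param path input file.
#' @param pixelSize micrometres per pixel to stamp on the fields.
#' @return list of [Field-class] frames.
#' @export
readFieldTiff <- function(path, pixelSize = 0.758) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) %% 2 != 0)
    stop("expected an even number of pages (red/green per frame)")
  lapply(seq_len(length(pages) / 2), function(t)
    Field(pages[[2 * t - 1]] * 65536, pages[[2 * t]] * 65536,
          pixelSize = pixelSize, time = t))
}

#' Write a label mask as 16-bit TIFF
#' @param mask integer label mask (values < 65536).
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeLabelMaskTiff <- function(mask, path) {
  stopifnot(max(mask) < 65536)
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16, reduce = FALSE)
  invisible(path)
}

#' Read a label mask written by [writeLabelMaskTiff()]
#' @param path input file.
#' @return integer label mask.
#' @export
readLabelMaskTiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Serialize a field specification to JSON
#' @param fs a [fieldSpec()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFieldSpecJson <- function(fs, path) {
  stopifnot(inherits(fs, "FieldSpec"))
  obj <- unclass(fs)
  obj$cells <- lapply(obj$cells, function(cl)
    list(spec = unclass(cl$spec), center = cl$center))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a field specification from JSON
#' @param path input file.
#' @return a `FieldSpec`.
#' @export
readFieldSpecJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  cells <- lapply(obj$cells, function(cl) {
    s <- cl$spec
    list(spec = shapeSpec(s$className, s$somaRadius, s$nProcesses,
                          s$processLength, s$processWidth, s$branchPoints,
                          s$intensityProfile, s$somaAspect, s$seed),
         center = unlist(cl$center))
  })
  particles <- lapply(obj$particles, function(pt)
    list(center = if (is.null(pt$center)) NULL else unlist(pt$center),
         radius = pt$radius,
         engulfedBy = if (is.null(pt$engulfedBy)) NA_integer_
                      else pt$engulfedBy))
  fieldSpec(unlist(obj$imageSize), pixelSize = obj$pixelSize,
            cells = cells, particles = particles,
            backgroundLevel = obj$backgroundLevel, noiseSd = obj$noiseSd,
            cellIntensity = obj$cellIntensity,
            particleIntensity = obj$particleIntensity,
            allowOverlap = isTRUE(obj$allowOverlap), seed = obj$seed)
}

#' Read mask edits from JSON
#'
#' Expected format: an array of objects with `kind` "split" (fields
#' `label`, `polyline` = array of [row, col]) or "merge" (field
#' `labels`).
#'
#' @param path input file.
#' @return list of `MaskEdit` records for [applyEdits()].
#' @export
readMaskEditsJson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(obj, function(e) {
    if (identical(e$kind, "merge")) maskEditMerge(unlist(e$labels))
    else if (identical(e$kind, "split"))
      maskEditSplit(e$label,
                    do.call(rbind, lapply(e$polyline, unlist)))
    else stop("unknown edit kind: ", e$kind)
  })
}
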