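#' Accessors for crop objects
#'
#' @param x a [CropImage-class] or [CropDataset-class].
#' @param i channel index or name.
#' @name crop-accessors
NULL

#' @rdname crop-accessors
#' @export
setGeneric("channels", function(x) standardGeneric("channels"))

#' @rdname crop-accessors
#' @export
setGeneric("channel", function(x, i = 1L) standardGeneric("channel"))

#' @rdname crop-accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname crop-accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname crop-accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname crop-accessors
#' @export
setGeneric("genotype", function(x) standardGeneric("genotype"))

#' @rdname crop-accessors
#' @export
setGeneric("cropId", function(x) standardGeneric("cropId"))

#' @rdname crop-accessors
#' @export
setGeneric("crops", function(x) standardGeneric("crops"))

#' @rdname crop-accessors
#' @export
setGeneric("cropIds", function(x) standardGeneric("cropIds"))

#' @rdname crop-accessors
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname crop-accessors
#' @export
setGeneric("excludedIds", function(x) standardGeneric("excludedIds"))

#' @rdname crop-accessors
#' @param value replacement value.
#' @export
setGeneric("excludedIds<-", function(x, value) standardGeneric("excludedIds<-"))

#' @rdname crop-accessors
#' @export
setGeneric("activeCrops", function(x) standardGeneric("activeCrops"))

setMethod("channels", "CropImage", function(x) x@channels)

setMethod("channel", "CropImage", function(x, i = 1L) {
  if (is.character(i)) i <- match(i, x@channelNames)
  if (is.na(i) || i < 1L || i > length(x@channels))
    stop("no such channel")
  x@channels[[i]]
})

setMethod("nChannels", "CropImage", function(x) length(x@channels))
setMethod("channelNames", "CropImage", function(x) x@channelNames)
setMethod("pixelSize", "CropImage", function(x) x@pixelSize)
setMethod("genotype", "CropImage", function(x) x@genotype)
setMethod("cropId", "CropImage", function(x) x@cropId)

setMethod("dim", "CropImage", function(x) dim(x@channels[[1L]]))

setMethod("show", "CropImage", function(object) {
  d <- dim(object)
  cat(sprintf(
    "CropImage '%s' (%s): %d x %d px, %d channel(s) [%s], %.3g um/px\n",
    object@cropId, object@genotype, d[1], d[2], nChannels(object),
    paste(object@channelNames, collapse = ", "), object@pixelSize
  ))
})

setMethod("crops", "CropDataset", function(x) x@crops)
setMethod("cropIds", "CropDataset",
  function(x) vapply(x@crops, cropId, character(1)))
setMethod("genotypes", "CropDataset",
  function(x) vapply(x@crops, genotype, character(1)))
setMethod("excludedIds", "CropDataset", function(x) x@excluded)

setReplaceMethod("excludedIds", "CropDataset", function(x, value) {
  x@excluded <- as.character(value)
  validObject(x)
  x
})

setMethod("activeCrops", "CropDataset", function(x) {
  keep <- !(cropIds(x) %in% x@excluded)
  x@crops[keep]
})

setMethod("length", "CropDataset", function(x) length(x@crops))

setMethod("[[", "CropDataset", function(x, i) {
  if (is.character(i)) i <- match(i, cropIds(x))
  if (is.na(i)) stop("no such crop")
  x@crops[[i]]
})

setMethod("show", "CropDataset", function(object) {
  g <- genotypes(object)
  cat(sprintf("CropDataset: %d crops, %d genotype(s), %d excluded\n",
              length(object), length(unique(g)), length(object@excluded)))
  if (length(g)) {
    tab <- table(g)
    for (nm in names(tab))
      cat(sprintf("  %s: %d crops\n", nm, tab[[nm]]))
  }
})

setMethod("show", "DetectionParams", function(object) {
  cat(sprintf("DetectionParams: method=%s, sensitivity=%.3g, neighborhood=%d\n",
              object@method, object@sensitivity, as.integer(object@neighborhood)))
})

setMethod("show", "RestrictionParams", function(object) {
  fmt <- function(x) if (is.na(x)) "off" else format(x)
  cat("RestrictionParams:\n")
  cat(sprintf("  edges: x=%d px, y=%d px\n",
              as.integer(object@xEdge), as.integer(object@yEdge)))
  cat(sprintf("  area [%s, %s] px^2; circularity [%s, %s]\n",
              fmt(object@minArea), fmt(object@maxArea),
              fmt(object@minCircularity), fmt(object@maxCircularity)))
  cat(sprintf("  length/width <= %s; variance [%s, %s]\n",
              fmt(object@maxLengthWidthRatio),
              fmt(object@minVariance), fmt(object@maxVariance)))
})

setMethod("show", "AnalysisConfig", function(object) {
  cat(sprintf("AnalysisConfig: %d channel(s) [%s], %.3g um/px, theta=%.2f, seed=%d\n",
              length(object@detection),
              paste(object@channelNames, collapse = ", "),
              object@pixelSize, object@overlapThreshold, object@rngSeed))
  for (i in seq_along(object@detection)) {
    cat(sprintf(" channel %d: ", i))
    show(object@detection[[i]])
  }
})
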