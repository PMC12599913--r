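#' @useDynLib punctakit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
NULL

#' CropImage: one straightened fluorescence crop
#'
#' A crop is a thin strip image cut out of a larger micrograph along a
#' neurite (typically ~20 px tall and a few hundred px long), carrying one or
#' two fluorescence channels plus its physical pixel size and bookkeeping
#' metadata. The first array axis is the crop height (the short, "y" axis),
#' the second axis runs along the neurite ("x").
#'
#' @slot channels list of one or two numeric matrices of identical dimensions
#'   (intensities in arbitrary units, stored as doubles).
#' @slot pixelSize physical pixel size in micrometers per pixel (> 0).
#' @slot genotype genotype (group) label.
#' @slot cropId unique identifier within a dataset.
#' @slot channelNames one name per channel.
#'
#' @seealso [CropImage()] for the constructor, [readCropDataset()]
#' @export
setClass("CropImage",
  slots = c(
    channels = "list",
    pixelSize = "numeric",
    genotype = "character",
    cropId = "character",
    channelNames = "character"
  )
)

setValidity("CropImage", function(object) {
  ch <- object@channels
  if (length(ch) < 1L || length(ch) > 2L)
    return("a crop must have 1 or 2 channels")
  if (!all(vapply(ch, is.matrix, logical(1))) ||
      !all(vapply(ch, is.numeric, logical(1))))
    return("channels must be numeric matrices")
  dims <- vapply(ch, dim, integer(2))
  if (length(ch) == 2L && !identical(dims[, 1], dims[, 2]))
    return("all channels must share one shape")
  if (any(dims < 1L))
    return("channel dimensions must be >= 1")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@channelNames) != length(ch))
    return("channelNames must have one entry per channel")
  if (length(object@genotype) != 1L || length(object@cropId) != 1L)
    return("genotype and cropId must be single strings")
  TRUE
})

#' Construct a CropImage
#'
#' @param channels a numeric matrix or a list of 1-2 numeric matrices with
#'   identical dimensions. Integer storage is cast to double without
#'   rescaling.
#' @param pixelSize micrometers per pixel.
#' @param genotype,cropId metadata labels.
#' @param channelNames optional channel names; defaults to
#'   `"channel1"`/`"channel2"`.
#' @return a [CropImage-class] object.
#' @examples
#' img <- matrix(runif(20 * 100), 20, 100)
#' crop <- CropImage(img, pixelSize = 0.21, genotype = "control", cropId = "c1")
#' nChannels(crop)
#' @export
CropImage <- function(channels, pixelSize, genotype = "unknown",
                      cropId = "crop", channelNames = NULL) {
  if (is.matrix(channels)) channels <- list(channels)
  channels <- lapply(channels, function(m) {
    storage.mode(m) <- "double"
    m
  })
  if (is.null(channelNames))
    channelNames <- paste0("channel", seq_along(channels))
  new("CropImage",
    channels = channels, pixelSize = as.numeric(pixelSize),
    genotype = as.character(genotype), cropId = as.character(cropId),
    channelNames = as.character(channelNames)
  )
}

#' CropDataset: an ordered collection of crops grouped by genotype
#'
#' @slot crops list of [CropImage-class] objects with unique `cropId`s,
#'   ordered by genotype then id.
#' @slot excluded character vector of cropIds flagged as outliers; excluded
#'   crops are skipped by summary-producing operations.
#' @seealso [readCropDataset()]
#' @export
setClass("CropDataset",
  slots = c(crops = "list", excluded = "character")
)

setValidity("CropDataset", function(object) {
  if (!all(vapply(object@crops, is, logical(1), "CropImage")))
    return("all elements must be CropImage objects")
  ids <- vapply(object@crops, function(x) x@cropId, character(1))
  if (anyDuplicated(ids))
    return("cropIds must be unique")
  if (length(object@excluded) && !all(object@excluded %in% ids))
    return("excluded ids must refer to crops in the dataset")
  TRUE
})

#' Construct a CropDataset
#' @param crops list of [CropImage-class] objects.
#' @param excluded character vector of excluded cropIds.
#' @return a [CropDataset-class].
#' @export
CropDataset <- function(crops = list(), excluded = character()) {
  new("CropDataset", crops = crops, excluded = as.character(excluded))
}

#' DetectionParams: thresholding settings for one channel
#'
#' The local-mean ("Bradley") threshold compares each pixel to the mean of a
#' square neighborhood around it, scaled by a sensitivity: pixel p is
#' foreground iff I(p) > mu_w(p) * 2 * (1 - s). Sensitivity lives in
#' \[0, 1\] and higher values are more permissive (larger foreground).
#'
#' @slot sensitivity threshold sensitivity in \[0, 1\].
#' @slot neighborhood odd window side length in pixels (>= 3).
#' @slot method `"local_means"` (adaptive) or `"global_otsu"` (baseline).
#' @export
setClass("DetectionParams",
  slots = c(sensitivity = "numeric", neighborhood = "numeric",
            method = "character"),
  prototype = list(sensitivity = 0.2, neighborhood = 15,
                   method = "local_means")
)

setValidity("DetectionParams", function(object) {
  s <- object@sensitivity
  w <- object@neighborhood
  if (length(s) != 1L || !is.finite(s) || s < 0 || s > 1)
    return("sensitivity must be a single value in [0, 1]")
  if (length(w) != 1L || !is.finite(w) || w < 3 || w %% 2 != 1)
    return("neighborhood must be a single odd integer >= 3")
  if (!object@method %in% c("local_means", "global_otsu"))
    return("method must be 'local_means' or 'global_otsu'")
  TRUE
})

#' @rdname DetectionParams-class
#' @param sensitivity,neighborhood,method see slots.
#' @return a [DetectionParams-class].
#' @export
DetectionParams <- function(sensitivity = 0.2, neighborhood = 15,
                            method = "local_means") {
  new("DetectionParams", sensitivity = as.numeric(sensitivity),
      neighborhood = as.numeric(neighborhood), method = method)
}

#' RestrictionParams: ROI exclusion rules
#'
#' ROIs are removed when any of their pixels falls inside the crop-edge
#' margin bands, or when an enabled feature bound is violated. A bound set
#' to `NA` is disabled. Defaults keep the edge exclusions at 0 and disable
#' all feature bounds except a minimum area of 5 px^2, a typical setting for
#' suppressing single-pixel noise.
#'
#' @slot xEdge,yEdge margin width in pixels at the left/right (x) and
#'   top/bottom (y) crop edges; ROIs with any pixel inside a margin are
#'   removed.
#' @slot minArea,maxArea area bounds in px^2.
#' @slot minCircularity,maxCircularity circularity (4*pi*A/P^2) bounds.
#' @slot maxLengthWidthRatio upper bound on the major/minor axis ratio of
#'   the second-moment ellipse.
#' @slot minVariance,maxVariance bounds on the within-ROI intensity variance.
#' @export
setClass("RestrictionParams",
  slots = c(
    xEdge = "numeric", yEdge = "numeric",
    minArea = "numeric", maxArea = "numeric",
    minCircularity = "numeric", maxCircularity = "numeric",
    maxLengthWidthRatio = "numeric",
    minVariance = "numeric", maxVariance = "numeric"
  ),
  prototype = list(
    xEdge = 0, yEdge = 0,
    minArea = 5, maxArea = NA_real_,
    minCircularity = NA_real_, maxCircularity = NA_real_,
    maxLengthWidthRatio = NA_real_,
    minVariance = NA_real_, maxVariance = NA_real_
  )
)

setValidity("RestrictionParams", function(object) {
  one <- function(x) length(x) == 1L && (is.na(x) || is.finite(x))
  for (nm in slotNames(object))
    if (!one(slot(object, nm)))
      return(sprintf("slot '%s' must be a single finite value or NA", nm))
  if (object@xEdge < 0 || object@yEdge < 0 ||
      is.na(object@xEdge) || is.na(object@yEdge))
    return("edge margins must be non-negative (not NA)")
  pairs <- list(c("minArea", "maxArea"),
                c("minCircularity", "maxCircularity"),
                c("minVariance", "maxVariance"))
  for (p in pairs) {
    lo <- slot(object, p[1]); hi <- slot(object, p[2])
    if (!is.na(lo) && !is.na(hi) && lo > hi)
      return(sprintf("%s must be <= %s", p[1], p[2]))
  }
  mlw <- object@maxLengthWidthRatio
  if (!is.na(mlw) && mlw < 1)
    return("maxLengthWidthRatio must be >= 1")
  cb <- c(object@minCircularity, object@maxCircularity)
  if (any(!is.na(cb) & (cb < 0 | cb > 1)))
    return("circularity bounds must lie in [0, 1]")
  TRUE
})

#' @rdname RestrictionParams-class
#' @param xEdge,yEdge,minArea,maxArea,minCircularity,maxCircularity
#'   see slots.
#' @param maxLengthWidthRatio,minVariance,maxVariance see slots.
#' @return a [RestrictionParams-class].
#' @export
RestrictionParams <- function(xEdge = 0, yEdge = 0,
                              minArea = 5, maxArea = NA,
                              minCircularity = NA, maxCircularity = NA,
                              maxLengthWidthRatio = NA,
                              minVariance = NA, maxVariance = NA) {
  new("RestrictionParams",
    xEdge = as.numeric(xEdge), yEdge = as.numeric(yEdge),
    minArea = as.numeric(minArea), maxArea = as.numeric(maxArea),
    minCircularity = as.numeric(minCircularity),
    maxCircularity = as.numeric(maxCircularity),
    maxLengthWidthRatio = as.numeric(maxLengthWidthRatio),
    minVariance = as.numeric(minVariance),
    maxVariance = as.numeric(maxVariance)
  )
}

#' AnalysisConfig: a complete, replayable analysis configuration
#'
#' Holds per-channel detection and restriction parameters plus the
#' dataset-level scalars. A config round-trips losslessly through JSON
#' ([saveConfig()] / [loadConfig()]); re-running an analysis with an
#' identical config on identical inputs yields bit-identical outputs.
#'
#' @slot detection list of one or two [DetectionParams-class] (per channel).
#' @slot restriction list of [RestrictionParams-class], same length.
#' @slot overlapThreshold ROI overlap threshold in \[0, 1\] used by the ROI
#'   Overlap Ratios.
#' @slot pixelSize micrometers per pixel.
#' @slot channelNames channel names, same length as `detection`.
#' @slot rngSeed integer seed used by any stochastic step.
#' @export
setClass("AnalysisConfig",
  slots = c(
    detection = "list",
    restriction = "list",
    overlapThreshold = "numeric",
    pixelSize = "numeric",
    channelNames = "character",
    rngSeed = "integer"
  )
)

setValidity("AnalysisConfig", function(object) {
  nd <- length(object@detection)
  if (nd < 1L || nd > 2L)
    return("config must cover 1 or 2 channels")
  if (!all(vapply(object@detection, is, logical(1), "DetectionParams")))
    return("detection must be a list of DetectionParams")
  if (length(object@restriction) != nd ||
      !all(vapply(object@restriction, is, logical(1), "RestrictionParams")))
    return("restriction must be a list of RestrictionParams, one per channel")
  th <- object@overlapThreshold
  if (length(th) != 1L || !is.finite(th) || th < 0 || th > 1)
    return("overlapThreshold must be a single value in [0, 1]")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number")
  if (length(object@channelNames) != nd)
    return("channelNames must have one entry per channel")
  if (length(object@rngSeed) != 1L || is.na(object@rngSeed))
    return("rngSeed must be a single integer")
  TRUE
})

#' @rdname AnalysisConfig-class
#' @param detection,restriction single objects or per-channel lists.
#' @param overlapThreshold,pixelSize,channelNames,rngSeed see slots.
#' @return an [AnalysisConfig-class].
#' @examples
#' cfg <- AnalysisConfig(
#'   detection = DetectionParams(sensitivity = 0.2, neighborhood = 15),
#'   restriction = RestrictionParams(yEdge = 3, minArea = 5),
#'   pixelSize = 0.21
#' )
#' cfg
#' @export
AnalysisConfig <- function(detection = DetectionParams(),
                           restriction = RestrictionParams(),
                           overlapThreshold = 0.3,
                           pixelSize = 0.21,
                           channelNames = NULL,
                           rngSeed = 1L) {
  if (is(detection, "DetectionParams")) detection <- list(detection)
  if (is(restriction, "RestrictionParams")) restriction <- list(restriction)
  if (length(restriction) == 1L && length(detection) == 2L)
    restriction <- rep(restriction, 2L)
  if (is.null(channelNames))
    channelNames <- paste0("channel", seq_along(detection))
  new("AnalysisConfig",
    detection = detection, restriction = restriction,
    overlapThreshold = as.numeric(overlapThreshold),
    pixelSize = as.numeric(pixelSize),
    channelNames = as.character(channelNames),
    rngSeed = as.integer(rngSeed)
  )
}
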