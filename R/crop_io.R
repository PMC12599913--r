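#' Read one crop from a TIFF file
#'
#' Multi-page TIFFs are interpreted as channels (page 1 = channel 1); at most
#' two pages are allowed. Integer pixel values are read as-is and cast to
#' double without rescaling; 32-bit float TIFFs keep their stored values.
#'
#' @param path path to a grayscale TIFF (8/16/32-bit, 1-2 pages).
#' @param pixelSize micrometers per pixel.
#' @param genotype,cropId metadata; default to the parent directory name and
#'   the filename stem.
#' @return a [CropImage-class].
#' @export
readCropTIFF <- function(path, pixelSize, genotype = NULL, cropId = NULL) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("unreadable or zero-sized image: ", path)
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE),
    error = function(e) tryCatch(
      tiff::readTIFF(path, all = TRUE),   # float sample format
      error = function(e2) stop("unreadable image: ", path, " (",
                                conditionMessage(e2), ")", call. = FALSE)
    )
  )
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) > 2L)
    stop("channel limit exceeded: ", path, " has ", length(pages),
         " pages (at most 2 channels supported)")
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) != 2L)
      stop("not a grayscale image: ", path)
    storage.mode(p) <- "double"
    p
  })
  if (is.null(genotype)) genotype <- basename(dirname(path))
  if (is.null(cropId)) cropId <- sub("\\.[^.]+$", "", basename(path))
  CropImage(pages, pixelSize = pixelSize, genotype = genotype, cropId = cropId)
}

#' Read a directory tree of crops into a CropDataset
#'
#' The root directory must contain one subdirectory per genotype; every
#' `.tif`/`.tiff` file inside becomes one crop. Ordering is deterministic:
#' genotypes and files are taken in lexicographic order, so repeated reads
#' of the same tree produce identically ordered datasets.
#'
#' @param root dataset root directory.
#' @param pixelSize micrometers per pixel (applies to the whole dataset).
#' @return a [CropDataset-class].
#' @examples
#' \dontrun{
#' ds <- readCropDataset("crops/", pixelSize = 0.21)
#' }
#' @export
readCropDataset <- function(root, pixelSize) {
  if (!dir.exists(root)) stop("no such directory: ", root)
  gdirs <- sort(list.dirs(root, recursive = FALSE))
  if (!length(gdirs)) stop("no genotype subdirectories under ", root)
  crops <- list()
  for (g in gdirs) {
    files <- sort(list.files(g, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    for (f in files)
      crops[[length(crops) + 1L]] <- readCropTIFF(f, pixelSize = pixelSize)
  }
  if (!length(crops)) stop("no TIFF crops found under ", root)
  # filename stems are the ids; qualify colliding stems by genotype
  ids <- vapply(crops, cropId, character(1))
  dup <- ids %in% ids[duplicated(ids)]
  for (i in which(dup))
    crops[[i]]@cropId <- paste(genotype(crops[[i]]), ids[i], sep = "/")
  CropDataset(crops)
}

#' Write a crop (or any matrix stack) as a TIFF
#'
#' Integer-valued data with all values in \[0, 65535\] is written losslessly
#' as 16-bit; other data is min-max scaled into \[0, 1\] and written as
#' 32-bit (relative precision ~2e-10), with a warning, because the TIFF
#' writer only supports unsigned-integer sample formats.
#'
#' @param x a [CropImage-class] or a numeric matrix / list of matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCropTIFF <- function(x, path) {
  if (is(x, "CropImage")) x <- channels(x)
  if (is.matrix(x)) x <- list(x)
  vals <- unlist(lapply(x, as.vector))
  if (all(vals >= 0) && all(vals <= 65535) && all(vals == round(vals))) {
    tiff::writeTIFF(lapply(x, function(m) m / 65535), path,
                    bits.per.sample = 16L)
  } else {
    warning("non-integral intensities: writing min-max scaled 32-bit TIFF")
    lo <- min(vals); hi <- max(vals)
    rng <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF(lapply(x, function(m) (m - lo) / rng), path,
                    bits.per.sample = 32L)
  }
  invisible(path)
}

#' Read or write a binary mask / label map TIFF
#'
#' Masks are single-page TIFFs where any nonzero pixel is foreground. Label
#' maps are written as 16-bit TIFFs holding the integer labels.
#'
#' @param path TIFF path.
#' @return `readMaskTIFF`: a logical matrix. `readLabelTIFF`: an integer
#'   matrix.
#' @export
readMaskTIFF <- function(path) {
  m <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                error = function(e) tiff::readTIFF(path))
  if (length(dim(m)) != 2L) stop("mask must be a single-page grayscale TIFF: ", path)
  m != 0
}

#' @rdname readMaskTIFF
#' @export
readLabelTIFF <- function(path) {
  m <- tiff::readTIFF(path, as.is = TRUE)
  if (length(dim(m)) != 2L) stop("label map must be single-page: ", path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname readMaskTIFF
#' @param labels integer label matrix (0 = background) or logical mask.
#' @export
writeLabelTIFF <- function(labels, path) {
  if (is.logical(labels)) labels <- labels * 1L
  if (max(labels) > 65535) stop("more than 65535 labels")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

## ---- configuration persistence ----------------------------------------

config_as_list <- function(config) {
  det <- lapply(config@detection, function(d) list(
    sensitivity = d@sensitivity,
    neighborhood_size = d@neighborhood,
    method = d@method
  ))
  res <- lapply(config@restriction, function(r) list(
    x_edge_px = r@xEdge, y_edge_px = r@yEdge,
    min_area_px2 = r@minArea, max_area_px2 = r@maxArea,
    min_circularity = r@minCircularity, max_circularity = r@maxCircularity,
    max_length_width_ratio = r@maxLengthWidthRatio,
    min_variance = r@minVariance, max_variance = r@maxVariance
  ))
  list(
    channel_names = as.list(config@channelNames),
    pixel_size_um = config@pixelSize,
    overlap_threshold = config@overlapThreshold,
    rng_seed = config@rngSeed,
    detection = det,
    restriction = res
  )
}

config_from_list <- function(x) {
  need <- function(obj, field, where = "config") {
    if (is.null(obj[[field]]))
      stop("config file is missing field '", field, "' (", where, ")")
    obj[[field]]
  }
  opt <- function(obj, field) {
    v <- obj[[field]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }
  det <- lapply(seq_along(need(x, "detection")), function(i) {
    d <- x$detection[[i]]
    w <- sprintf("detection[%d]", i)
    DetectionParams(
      sensitivity = need(d, "sensitivity", w),
      neighborhood = need(d, "neighborhood_size", w),
      method = need(d, "method", w)
    )
  })
  res <- lapply(seq_along(need(x, "restriction")), function(i) {
    r <- x$restriction[[i]]
    w <- sprintf("restriction[%d]", i)
    RestrictionParams(
      xEdge = need(r, "x_edge_px", w), yEdge = need(r, "y_edge_px", w),
      minArea = opt(r, "min_area_px2"), maxArea = opt(r, "max_area_px2"),
      minCircularity = opt(r, "min_circularity"),
      maxCircularity = opt(r, "max_circularity"),
      maxLengthWidthRatio = opt(r, "max_length_width_ratio"),
      minVariance = opt(r, "min_variance"),
      maxVariance = opt(r, "max_variance")
    )
  })
  AnalysisConfig(
    detection = det, restriction = res,
    overlapThreshold = need(x, "overlap_threshold"),
    pixelSize = need(x, "pixel_size_um"),
    channelNames = unlist(need(x, "channel_names")),
    rngSeed = need(x, "rng_seed")
  )
}

#' Save / load an analysis configuration as JSON
#'
#' The JSON schema mirrors the [AnalysisConfig-class] slots with explicit
#' defaults for every field; `loadConfig(saveConfig(cfg))` reproduces the
#' configuration field-for-field, so a saved config replays a previous
#' analysis exactly. Disabled restriction bounds are stored as `null`.
#'
#' @param config an [AnalysisConfig-class].
#' @param path JSON file path.
#' @return `saveConfig`: `path`, invisibly. `loadConfig`: an
#'   [AnalysisConfig-class]. A file with missing fields raises an error
#'   naming the field.
#' @examples
#' f <- tempfile(fileext = ".json")
#' saveConfig(AnalysisConfig(), f)
#' loadConfig(f)
#' @export
saveConfig <- function(config, path) {
  stopifnot(is(config, "AnalysisConfig"))
  validObject(config)
  jsonlite::write_json(config_as_list(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname saveConfig
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- config_from_list(x)
  validObject(cfg)
  cfg
}
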