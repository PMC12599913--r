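#' Measure per-ROI features
#'
#' Computes, for every label in a label map, the features used by the
#' restriction filters and the output tables:
#' \itemize{
#'   \item `area_px2`, `area_um2` (area_um2 = area_px2 * pixelSize^2)
#'   \item `sum_intensity`, `mean_intensity`, `max_intensity`
#'   \item centroid (`centroid_row`, `centroid_col`, 1-based pixel centers)
#'   \item `circularity` = 4*pi*A/P^2, with the perimeter P counted as the
#'     number of 4-connected boundary edges (edges between an ROI pixel and
#'     a non-ROI pixel or the image border); a single-pixel ROI is defined
#'     to have circularity 1
#'   \item `length_width_ratio`: sqrt of the ratio of the eigenvalues of the
#'     pixel-coordinate covariance matrix, with 1/12 added to each diagonal
#'     term to account for the unit pixel extent (so a 1 x n bar scores
#'     exactly n and a single pixel exactly 1)
#'   \item `intensity_variance`: population variance of the ROI's pixel
#'     intensities (0 for a single pixel)
#'   \item bounding box (`min_row`..`max_col`) and whether the ROI touches
#'     the crop border (`touches_x_edge`, `touches_y_edge`)
#' }
#'
#' @param labels integer label matrix with contiguous labels 1..K.
#' @param channel intensity matrix, same shape.
#' @param pixelSize micrometers per pixel.
#' @return a `data.frame` with one row per label, ordered by label.
#' @export
measureROIs <- function(labels, channel, pixelSize) {
  stopifnot(is.matrix(labels), is.matrix(channel))
  if (!identical(dim(labels), dim(channel)))
    stop("labels and channel shapes differ")
  K <- max(labels)
  if (K == 0L)
    return(empty_roi_table())
  present <- sort(unique(labels[labels > 0]))
  if (!identical(as.integer(present), seq_len(K)))
    stop("labels must be contiguous 1..K (gaps found)")

  idx <- which(labels > 0)
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  rr <- rc[, 1]; cc <- rc[, 2]
  v <- channel[idx]
  f <- factor(lab, levels = seq_len(K))

  area <- as.integer(tabulate(lab, nbins = K))
  s <- as.numeric(tapply(v, f, sum))
  mx <- as.numeric(tapply(v, f, max))
  mean_i <- s / area
  varp <- as.numeric(tapply(v, f, function(z) mean((z - mean(z))^2)))
  cen_r <- as.numeric(tapply(rr, f, mean))
  cen_c <- as.numeric(tapply(cc, f, mean))

  # 4-connected boundary-edge perimeter, per label
  per <- perimeter_by_label(labels, K)
  circ <- ifelse(area == 1L, 1, 4 * pi * area / per^2)

  lw <- lw_ratio_by_label(rr, cc, f, area)

  min_r <- as.integer(tapply(rr, f, min)); max_r <- as.integer(tapply(rr, f, max))
  min_c <- as.integer(tapply(cc, f, min)); max_c <- as.integer(tapply(cc, f, max))

  data.frame(
    label = seq_len(K),
    area_px2 = area,
    area_um2 = area * pixelSize^2,
    sum_intensity = s,
    mean_intensity = mean_i,
    max_intensity = mx,
    centroid_row = cen_r,
    centroid_col = cen_c,
    circularity = circ,
    length_width_ratio = lw,
    intensity_variance = varp,
    min_row = min_r, max_row = max_r, min_col = min_c, max_col = max_c,
    touches_x_edge = min_c == 1L | max_c == ncol(labels),
    touches_y_edge = min_r == 1L | max_r == nrow(labels)
  )
}

empty_roi_table <- function() {
  data.frame(
    label = integer(), area_px2 = integer(), area_um2 = numeric(),
    sum_intensity = numeric(), mean_intensity = numeric(),
    max_intensity = numeric(), centroid_row = numeric(),
    centroid_col = numeric(), circularity = numeric(),
    length_width_ratio = numeric(), intensity_variance = numeric(),
    min_row = integer(), max_row = integer(), min_col = integer(),
    max_col = integer(), touches_x_edge = logical(),
    touches_y_edge = logical()
  )
}

# boundary edges between each label and anything that is not that label
# (other labels, background, or the image border), counted per 4-neighbor
perimeter_by_label <- function(labels, K) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(0L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  edges <- numeric(K)
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
    diff <- core > 0 & nb != core
    edges <- edges + tabulate(core[diff], nbins = K)
  }
  edges
}

lw_ratio_by_label <- function(rr, cc, f, area) {
  mr <- as.numeric(tapply(rr, f, mean))
  mc <- as.numeric(tapply(cc, f, mean))
  vr <- as.numeric(tapply(rr^2, f, mean)) - mr^2 + 1 / 12
  vc <- as.numeric(tapply(cc^2, f, mean)) - mc^2 + 1 / 12
  cv <- as.numeric(tapply(rr * cc, f, mean)) - mr * mc
  tr <- vr + vc
  det <- vr * vc - cv^2
  disc <- sqrt(pmax(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  sqrt(l1 / pmax(l2, .Machine$double.eps))
}

#' Apply edge and feature restriction filters to a label map
#'
#' An ROI is removed iff (a) any of its pixels lies within `xEdge` pixels of
#' the left/right crop edge or within `yEdge` pixels of the top/bottom edge,
#' or (b) any enabled feature bound (area, circularity, length-width ratio,
#' intensity variance) is violated. Removal decisions are evaluated
#' independently per ROI, so the result does not depend on ordering and the
#' operation is idempotent. Survivors are relabeled contiguously, preserving
#' their original order.
#'
#' @param labels integer label matrix (contiguous labels).
#' @param table the matching [measureROIs()] table.
#' @param params a [RestrictionParams-class].
#' @return a list with `labels` (relabeled matrix), `table` (surviving rows,
#'   relabeled, with the original label kept in `original_label`), and
#'   `removed` (the removed original labels).
#' @examples
#' labels <- matrix(0L, 10, 20); labels[9:10, 5:6] <- 1L; labels[3:5, 12:14] <- 2L
#' tab <- measureROIs(labels, matrix(1, 10, 20), 0.21)
#' res <- restrictROIs(labels, tab, RestrictionParams(yEdge = 3, minArea = 0))
#' res$removed  # the ROI touching the bottom edge
#' @export
restrictROIs <- function(labels, table, params = RestrictionParams()) {
  validObject(params)
  if (nrow(table) != max(0L, max(labels)))
    stop("table does not correspond to labels")
  if (nrow(table) == 0L)
    return(list(labels = labels, table = cbind(table, original_label = integer()),
                removed = integer()))
  keep <- roi_keep_predicate(table, params, dim(labels))
  old <- table$label[keep]
  map <- integer(nrow(table))
  map[old] <- seq_along(old)
  newlab <- array(0L, dim = dim(labels))
  pos <- labels > 0 & array(labels %in% old, dim = dim(labels))
  newlab[pos] <- map[labels[pos]]
  tab <- table[keep, , drop = FALSE]
  tab$original_label <- tab$label
  tab$label <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  list(labels = newlab, table = tab, removed = table$label[!keep])
}

# TRUE = ROI survives. Exactly the per-ROI predicate; kept separate so it
# can be tested against brute-force evaluation.
roi_keep_predicate <- function(table, params, dims) {
  nr <- dims[1]; nc <- dims[2]
  xe <- params@xEdge; ye <- params@yEdge
  in_x_margin <- table$min_col <= xe | table$max_col > nc - xe
  in_y_margin <- table$min_row <= ye | table$max_row > nr - ye
  bad <- in_x_margin | in_y_margin
  chk <- function(bad, value, lo, hi) {
    if (!is.na(lo)) bad <- bad | value < lo
    if (!is.na(hi)) bad <- bad | value > hi
    bad
  }
  bad <- chk(bad, table$area_px2, params@minArea, params@maxArea)
  bad <- chk(bad, table$circularity, params@minCircularity, params@maxCircularity)
  bad <- chk(bad, table$length_width_ratio, NA, params@maxLengthWidthRatio)
  bad <- chk(bad, table$intensity_variance, params@minVariance, params@maxVariance)
  !bad
}

#' ROI count normalized to 100 micrometers of crop length
#'
#' @param nRois ROI count.
#' @param cropLengthPx crop length in pixels (the long axis), >= 1.
#' @param pixelSize micrometers per pixel.
#' @return `nRois / (cropLengthPx * pixelSize) * 100`.
#' @export
countPer100um <- function(nRois, cropLengthPx, pixelSize) {
  if (cropLengthPx < 1) stop("crop length must be >= 1 pixel")
  nRois / (cropLengthPx * pixelSize) * 100
}

#' Signal-to-noise ratio of a segmentation
#'
#' The ratio of summed intensity inside ROI pixels to summed intensity
#' outside them. An empty mask returns 0; a zero background intensity sum is
#' an error (the ratio is undefined).
#'
#' @param channel intensity matrix.
#' @param mask logical ROI mask, same shape.
#' @return a single number.
#' @export
snr <- function(channel, mask) {
  stopifnot(identical(dim(channel), dim(mask)))
  mask <- mask != 0
  if (!any(mask)) return(0)
  bg <- sum(channel[!mask])
  if (bg == 0) stop("background intensity sum is zero; SNR undefined")
  sum(channel[mask]) / bg
}
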