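#' Pearson correlation between two channels
#'
#' Pearson correlation coefficient over all crop pixels of the two intensity
#' channels (no masking; in this workflow the crop itself is the
#' background-minimizing step). Errors on constant channels, where the
#' denominator vanishes.
#'
#' @param ch1,ch2 intensity matrices of identical shape.
#' @return a value in \[-1, 1\].
#' @export
pcc <- function(ch1, ch2) {
  stopifnot(identical(dim(ch1), dim(ch2)))
  if (min(ch1) == max(ch1) || min(ch2) == max(ch2))
    stop("PCC undefined for a constant channel")
  stats::cor(as.vector(ch1), as.vector(ch2))
}

#' @rdname pcc
#' @details `pccNormalized` maps the coefficient to \[0, 1\] via
#'   (pcc + 1) / 2, making it directly comparable with the Manders and ROI
#'   Overlap metrics (which already span \[0, 1\]); this is the scale used
#'   by [noiseStudy()].
#' @export
pccNormalized <- function(ch1, ch2) (pcc(ch1, ch2) + 1) / 2

#' Binary Manders coefficients
#'
#' Pixel-count overlap fractions of two thresholded masks:
#' M1 = |mask1 & mask2| / |mask1| (the fraction of channel-1 signal pixels
#' that are also signal in channel 2) and M2 the reverse. These are the
#' binary-indicator forms; they are not the classic intensity-weighted
#' Manders coefficients.
#'
#' @param mask1,mask2 logical matrices of identical shape, each non-empty.
#' @return named numeric vector `c(m1 = , m2 = )`.
#' @examples
#' a <- matrix(FALSE, 4, 4); b <- a
#' a[1, 1:2] <- TRUE; b[1, 2:3] <- TRUE
#' manders(a, b)  # c(m1 = 0.5, m2 = 0.5)
#' @export
manders <- function(mask1, mask2) {
  stopifnot(identical(dim(mask1), dim(mask2)))
  mask1 <- mask1 != 0; mask2 <- mask2 != 0
  n1 <- sum(mask1); n2 <- sum(mask2)
  if (n1 == 0L) stop("M1 undefined: channel 1 has no signal pixels")
  if (n2 == 0L) stop("M2 undefined: channel 2 has no signal pixels")
  ov <- sum(mask1 & mask2)
  c(m1 = ov / n1, m2 = ov / n2)
}

#' ROI Overlap Ratio
#'
#' Object-level colocalization: an ROI of the label map counts as
#' colocalized iff the fraction of its pixels that are signal in the other
#' channel is at least `theta` (inclusive) *and* greater than zero -- so at
#' theta = 0 an ROI with no overlapping pixel is still not colocalized. The
#' returned ratio is the colocalized fraction of ROIs. Call it once per
#' direction (labels of channel 1 against the mask of channel 2 gives R1;
#' swap for R2).
#'
#' @param labels integer label map (contiguous labels, >= 1 ROI).
#' @param otherMask logical signal mask of the other channel.
#' @param theta overlap threshold in \[0, 1\].
#' @return the fraction of ROIs classified as colocalized.
#' @export
roiOverlapRatio <- function(labels, otherMask, theta) {
  stopifnot(identical(dim(labels), dim(otherMask)))
  if (theta < 0 || theta > 1) stop("theta must lie in [0, 1]")
  K <- max(labels)
  if (K == 0L) stop("no ROIs in label map")
  otherMask <- otherMask != 0
  idx <- labels > 0
  lab <- labels[idx]
  area <- tabulate(lab, nbins = K)
  ov <- tabulate(lab[otherMask[idx]], nbins = K)
  frac <- ov / area
  mean(frac >= theta & ov > 0)
}

#' Colocalization metrics for one two-channel crop
#'
#' Computes the three metric families on a pair of analyzed channels: PCC on
#' raw intensities, binary Manders coefficients on the (restricted) signal
#' masks, and ROI Overlap Ratios on the (restricted) label maps, each
#' channel's ROIs scored against the other channel's label support.
#'
#' @param ch1,ch2 intensity matrices.
#' @param labels1,labels2 restricted label maps of the two channels.
#' @param theta overlap threshold.
#' @return one-row `data.frame` with columns `pcc`, `pcc_normalized`, `m1`,
#'   `m2`, `r1`, `r2`, `overlap_threshold`.
#' @export
colocalizeCrop <- function(ch1, ch2, labels1, labels2, theta = 0.3) {
  m <- manders(labels1 > 0, labels2 > 0)
  p <- pcc(ch1, ch2)
  data.frame(
    pcc = p,
    pcc_normalized = (p + 1) / 2,
    m1 = unname(m["m1"]), m2 = unname(m["m2"]),
    r1 = roiOverlapRatio(labels1, labels2 > 0, theta),
    r2 = roiOverlapRatio(labels2, labels1 > 0, theta),
    overlap_threshold = theta
  )
}

#' ROI Overlap Ratio as a function of the overlap threshold
#'
#' Evaluates R1 and R2 on a grid of overlap thresholds for a set of
#' two-channel crops and aggregates per genotype (mean and SD). Crops whose
#' metrics cannot be computed (e.g., a channel without ROIs) are recorded as
#' missing with a warning. Both curves are non-increasing in theta.
#'
#' @param labelPairs list, one element per crop, each a
#'   `list(labels1 = , labels2 = )` of restricted label maps.
#' @param thetas sorted numeric grid of overlap thresholds in \[0, 1\].
#' @param genotype character vector, one genotype per crop.
#' @param cropId optional crop identifiers.
#' @return list with `perCrop` (long `data.frame`: crop_id, genotype, theta,
#'   r1, r2) and `summary` (genotype x theta means and SDs).
#' @export
overlapCurve <- function(labelPairs, thetas, genotype = NULL, cropId = NULL) {
  stopifnot(!is.unsorted(thetas))
  n <- length(labelPairs)
  if (is.null(genotype)) genotype <- rep("all", n)
  if (is.null(cropId)) cropId <- sprintf("crop%03d", seq_len(n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    lp <- labelPairs[[i]]
    vals <- tryCatch({
      r1 <- vapply(thetas, function(th)
        roiOverlapRatio(lp$labels1, lp$labels2 > 0, th), numeric(1))
      r2 <- vapply(thetas, function(th)
        roiOverlapRatio(lp$labels2, lp$labels1 > 0, th), numeric(1))
      list(r1 = r1, r2 = r2)
    }, error = function(e) {
      warning("crop ", cropId[i], ": ", conditionMessage(e),
              " (recorded as missing)", call. = FALSE)
      list(r1 = rep(NA_real_, length(thetas)),
           r2 = rep(NA_real_, length(thetas)))
    })
    rows[[i]] <- data.frame(
      crop_id = cropId[i], genotype = genotype[i], theta = thetas,
      r1 = vals$r1, r2 = vals$r2
    )
  }
  perCrop <- do.call(rbind, rows)
  agg <- function(v) c(mean = mean(v, na.rm = TRUE),
                       sd = stats::sd(v, na.rm = TRUE))
  sp <- split(perCrop, list(perCrop$genotype, perCrop$theta), drop = TRUE)
  summary <- do.call(rbind, lapply(sp, function(d) {
    a1 <- agg(d$r1); a2 <- agg(d$r2)
    data.frame(genotype = d$genotype[1], theta = d$theta[1],
               r1_mean = a1["mean"], r1_sd = a1["sd"],
               r2_mean = a2["mean"], r2_sd = a2["sd"])
  }))
  summary <- summary[order(summary$genotype, summary$theta), ]
  rownames(summary) <- NULL
  list(perCrop = perCrop, summary = summary)
}
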