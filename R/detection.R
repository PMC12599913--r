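#' Min-max normalize an intensity image to \[0, 1\]
#'
#' Rescales over the whole crop: (I - min) / (max - min). A constant image
#' maps to all zeros (the degenerate case carries no contrast to preserve).
#'
#' @param channel numeric matrix of finite intensities.
#' @return numeric matrix in \[0, 1\].
#' @export
normalizeImage <- function(channel) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (!all(is.finite(channel)))
    stop("channel contains non-finite pixels")
  lo <- min(channel); hi <- max(channel)
  if (hi == lo) return(array(0, dim = dim(channel)))
  (channel - lo) / (hi - lo)
}

# Mean over a w x w window centered at each pixel, with edge-replicated
# padding, via a summed-area table on the padded image. Exactly the
# per-pixel windowed mean, O(1) per pixel.
local_window_mean <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x)
  h <- (w - 1L) %/% 2L
  xp <- x[pmin(pmax(seq_len(nr + 2 * h) - h, 1L), nr),
          pmin(pmax(seq_len(nc + 2 * h) - h, 1L), nc), drop = FALSE]
  # summed-area table with a leading zero row/column
  S <- rbind(0, apply(xp, 2, cumsum))
  S <- cbind(0, t(apply(S, 1, cumsum)))
  r1 <- seq_len(nr); c1 <- seq_len(nc)        # top-left corner in padded coords
  r2 <- r1 + w; c2 <- c1 + w                  # bottom-right + 1
  (S[r2, c2] - S[r1, c2] - S[r2, c1] + S[r1, c1]) / (w * w)
}

#' Adaptive local-mean (Bradley) thresholding
#'
#' Each pixel is compared against the mean of the `neighborhood` x
#' `neighborhood` window centered on it (windows overhanging the crop edge
#' are filled by replicating border pixels). Pixel p becomes foreground iff
#'
#'   I(p) > mu_w(p) * 2 * (1 - s)
#'
#' where s is the sensitivity in \[0, 1\]. Higher sensitivities lower the
#' threshold and are therefore more permissive; masks are nested in s. At
#' s = 0.5 a pixel is kept exactly when it exceeds its local mean. The
#' inequality is strict, so constant (e.g., all-zero) regions never produce
#' foreground.
#'
#' @param channel numeric intensity matrix.
#' @param sensitivity value in \[0, 1\], or a [DetectionParams-class] (in
#'   which case `neighborhood` is ignored).
#' @param neighborhood odd window side length in pixels, >= 3.
#' @return logical matrix, `TRUE` = foreground.
#' @examples
#' img <- matrix(0, 7, 7); img[4, 4] <- 100
#' sum(bradleyThreshold(img, sensitivity = 0.5, neighborhood = 3))  # 1
#' @export
bradleyThreshold <- function(channel, sensitivity = 0.2, neighborhood = 15) {
  if (is(sensitivity, "DetectionParams")) {
    neighborhood <- sensitivity@neighborhood
    sensitivity <- sensitivity@sensitivity
  }
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (length(channel) == 0L) stop("empty image")
  if (!all(is.finite(channel))) stop("channel contains non-finite pixels")
  if (neighborhood %% 2 != 1 || neighborhood < 3)
    stop("neighborhood must be an odd integer >= 3")
  if (sensitivity < 0 || sensitivity > 1)
    stop("sensitivity must lie in [0, 1]")
  mu <- local_window_mean(channel, as.integer(neighborhood))
  channel > mu * 2 * (1 - sensitivity)
}

#' Global Otsu thresholding (baseline)
#'
#' Picks the single global threshold that maximizes the between-class
#' variance on a 256-bin histogram of the min-max normalized image
#' (delegated to [EBImage::otsu()]); foreground is strictly above the
#' threshold. A constant image yields an empty mask, since no threshold can
#' separate classes.
#'
#' @param channel numeric intensity matrix.
#' @return logical matrix, `TRUE` = foreground.
#' @export
otsuThreshold <- function(channel) {
  stopifnot(is.matrix(channel), is.numeric(channel))
  if (!all(is.finite(channel))) stop("channel contains non-finite pixels")
  if (min(channel) == max(channel))
    return(array(FALSE, dim = dim(channel)))
  nim <- normalizeImage(channel)
  th <- EBImage::otsu(nim, range = c(0, 1), levels = 256)
  nim > th
}

#' Label 8-connected foreground components
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer label matrix with contiguous labels 1..K, 0 = background.
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  .cpp_label_components(mask != 0, as.integer(connectivity))
}

#' Watershed segmentation of thresholded puncta
#'
#' Splits touching puncta inside a binary mask using both the distance to
#' the mask edge and the pixel intensity. The elevation map is
#'
#'   E = -(D * normImg)
#'
#' where D is the Euclidean distance from each foreground pixel to the
#' nearest background pixel (0 on background) and normImg the min-max
#' normalized channel. Watershed flooding starts from the regional minima of
#' E within the mask (a connected plateau of minimal elevation is a single
#' seed) and proceeds in order of increasing elevation; pixels where basins
#' meet are ridge pixels and are left as background (0) in the output.
#' A connected foreground region holding a single regional minimum comes
#' back as a single label.
#'
#' @param mask logical foreground matrix.
#' @param channel intensity matrix of the same shape.
#' @return integer label matrix (contiguous labels 1..K, ridge and
#'   background pixels 0). Every labeled pixel was foreground in `mask`.
#' @seealso [bradleyThreshold()], [detectROIs()]
#' @export
segmentROIs <- function(mask, channel) {
  stopifnot(is.matrix(mask), is.matrix(channel))
  if (!identical(dim(mask), dim(channel)))
    stop("mask and channel shapes differ")
  mask <- mask != 0
  if (!any(mask)) return(array(0L, dim = dim(mask)))
  nim <- normalizeImage(channel)
  D <- EBImage::distmap(mask * 1, metric = "euclidean")
  D <- as.matrix(D)
  # an all-foreground image has no background to measure distance to
  D[is.infinite(D)] <- sum(dim(mask))
  elev <- -(D * nim)
  .cpp_watershed(elev, mask)
}

#' Threshold and segment one channel
#'
#' Convenience wrapper: applies the configured thresholding method
#' (local-mean or global Otsu) and then the watershed split.
#'
#' @param channel intensity matrix.
#' @param params a [DetectionParams-class].
#' @return a list with elements `mask` (logical) and `labels` (integer
#'   label matrix).
#' @export
detectROIs <- function(channel, params = DetectionParams()) {
  validObject(params)
  mask <- switch(params@method,
    local_means = bradleyThreshold(channel, params@sensitivity,
                                   params@neighborhood),
    global_otsu = otsuThreshold(channel),
    stop("unknown method: ", params@method)
  )
  list(mask = mask, labels = segmentROIs(mask, channel))
}
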