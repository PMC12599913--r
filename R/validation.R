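#' Confusion rates of a predicted mask against ground truth
#'
#' Pixel-level sensitivity (TPR), specificity (TNR) and their mean, the
#' balanced accuracy (BA), of a predicted foreground mask against a
#' ground-truth mask. TPR is the fraction of ground-truth ROI pixels the
#' prediction recovers; TNR the fraction of ground-truth background pixels
#' the prediction leaves as background; BA = (TPR + TNR) / 2 exactly.
#'
#' In `column1d` mode both masks are first collapsed column-wise -- a column
#' is positive if it contains at least one foreground pixel -- and the rates
#' are computed on the resulting 1 x width masks. This is the mode used to
#' compare 1D profile-based baselines, which cannot assign individual
#' pixels.
#'
#' @param pred,truth logical matrices of identical shape.
#' @param mode `"pixel2d"` (default) or `"column1d"`.
#' @return named list with `tpr`, `tnr`, `balanced_accuracy`, `mode`.
#'   Truth with zero positives (or zero negatives) is an error, since the
#'   corresponding rate is undefined.
#' @export
confusionRates <- function(pred, truth, mode = c("pixel2d", "column1d")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(pred), dim(truth)))
  pred <- pred != 0; truth <- truth != 0
  if (mode == "column1d") {
    pred <- matrix(colSums(pred) > 0, nrow = 1)
    truth <- matrix(colSums(truth) > 0, nrow = 1)
  }
  P <- sum(truth); N <- sum(!truth)
  if (P == 0L) stop("TPR undefined: ground truth has no positive pixels")
  if (N == 0L) stop("TNR undefined: ground truth has no negative pixels")
  tp <- sum(pred & truth)
  tn <- sum(!pred & !truth)
  tpr <- tp / P
  tnr <- tn / N
  list(tpr = tpr, tnr = tnr, balanced_accuracy = (tpr + tnr) / 2, mode = mode)
}

#' 1D sum-projection peak finding (baseline)
#'
#' The classical plot-profile baseline: the crop is collapsed to a 1D
#' profile by summing each column, and peaks of the profile stand in for
#' puncta. A peak is a strict local maximum (a plateau of equal values
#' flanked by lower values counts once, at its middle column) that passes
#' three filters: prominence >= `minProminence`, width at half prominence
#' <= `maxWidthCols`, and height >= `noiseToSignalRatio` * median(profile).
#' Each surviving peak claims the contiguous column interval over which the
#' profile stays above the half-prominence level.
#'
#' @param channel intensity matrix (crop).
#' @param minProminence minimum peak prominence (profile units).
#' @param maxWidthCols maximum width at half prominence, in columns.
#' @param noiseToSignalRatio height floor as a multiple of the profile
#'   median (0 disables the filter).
#' @return `data.frame` with one row per peak: `position`, `height`,
#'   `prominence`, `width`, `left`, `right` (the claimed column interval).
#'   A flat profile yields zero rows.
#' @seealso [peaksToMask()] to convert the peak list to a column mask.
#' @export
findProfilePeaks <- function(channel, minProminence = 0,
                             maxWidthCols = Inf, noiseToSignalRatio = 0) {
  stopifnot(is.matrix(channel), nrow(channel) >= 1)
  profile <- colSums(channel)
  n <- length(profile)
  empty <- data.frame(position = integer(), height = numeric(),
                      prominence = numeric(), width = integer(),
                      left = integer(), right = integer())
  if (n < 3 || min(profile) == max(profile)) return(empty)

  # strict local maxima with plateau handling
  peaks <- integer()
  i <- 2L
  while (i <= n - 1L) {
    if (profile[i] > profile[i - 1L]) {
      j <- i
      while (j < n && profile[j + 1L] == profile[i]) j <- j + 1L
      if (j < n && profile[j + 1L] < profile[i])
        peaks <- c(peaks, (i + j) %/% 2L)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(peaks)) return(empty)

  heights <- profile[peaks]
  prom <- vapply(peaks, function(p) peak_prominence(profile, p), numeric(1))
  med <- stats::median(profile)

  rows <- lapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    level <- heights[k] - prom[k] / 2
    l <- p; while (l > 1L && profile[l - 1L] >= level) l <- l - 1L
    r <- p; while (r < n && profile[r + 1L] >= level) r <- r + 1L
    data.frame(position = p, height = heights[k], prominence = prom[k],
               width = r - l + 1L, left = l, right = r)
  })
  out <- do.call(rbind, rows)
  keep <- out$prominence >= minProminence &
    out$width <= maxWidthCols &
    out$height >= noiseToSignalRatio * med
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# standard topographic prominence: drop from the peak to the highest of the
# two key saddles (walking out each side until a strictly higher point, or
# the end of the profile)
peak_prominence <- function(profile, p) {
  n <- length(profile)
  h <- profile[p]
  left_min <- h
  i <- p - 1L
  while (i >= 1L && profile[i] <= h) {
    if (profile[i] < left_min) left_min <- profile[i]
    i <- i - 1L
  }
  if (i < 1L) left_min <- min(profile[1:p])
  right_min <- h
  i <- p + 1L
  while (i <= n && profile[i] <= h) {
    if (profile[i] < right_min) right_min <- profile[i]
    i <- i + 1L
  }
  if (i > n) right_min <- min(profile[p:n])
  h - max(left_min, right_min)
}

#' Convert a peak list to a column-mode mask
#'
#' @param peaks a [findProfilePeaks()] table.
#' @param width crop width (number of columns).
#' @param height number of rows for the output mask (default 1).
#' @return logical matrix where the claimed columns are `TRUE` in every row,
#'   directly comparable with [confusionRates()] in `column1d` mode.
#' @export
peaksToMask <- function(peaks, width, height = 1L) {
  cols <- logical(width)
  for (k in seq_len(nrow(peaks)))
    cols[peaks$left[k]:peaks$right[k]] <- TRUE
  matrix(rep(cols, each = height), nrow = height)
}

#' Threshold-sensitivity robustness sweep
#'
#' Re-runs the full detection pipeline (threshold, watershed, restriction)
#' over a grid of sensitivities centered on the configured optimum
#' (optimum +/- `halfRange` in steps of `step`, clipped to \[0, 1\]), and
#' records per-crop ROI counts, counts per 100 um, and a Welch one-way
#' ANOVA p-value across genotypes at every grid point. A study whose
#' conclusion (which genotypes differ) is stable across the grid is not
#' over-optimized to one sensitivity setting.
#'
#' @param dataset a [CropDataset-class]; excluded crops are skipped.
#'   Genotypes with fewer than 2 crops are dropped from the ANOVA with a
#'   warning.
#' @param config an [AnalysisConfig-class]; `channel` selects which
#'   channel's detection settings are swept.
#' @param halfRange half-width of the sensitivity interval (default 0.15,
#'   i.e., a total interval of 0.3 out of the possible 0-1).
#' @param step grid step (default 0.01).
#' @param channel channel index to sweep.
#' @return list with `grid` (the sensitivities), `counts` (long
#'   `data.frame`: sensitivity, crop_id, genotype, n_rois, count_per_100um)
#'   and `anova` (`data.frame`: sensitivity, p_value from
#'   [stats::oneway.test()] with `var.equal = FALSE`).
#' @export
sensitivitySweep <- function(dataset, config, halfRange = 0.15, step = 0.01,
                             channel = 1L) {
  stopifnot(is(dataset, "CropDataset"), is(config, "AnalysisConfig"))
  dpar <- config@detection[[channel]]
  rpar <- config@restriction[[channel]]
  s0 <- dpar@sensitivity
  grid <- seq(s0 - halfRange, s0 + halfRange, by = step)
  grid <- round(grid[grid >= 0 & grid <= 1], 10)

  use <- activeCrops(dataset)
  gt <- vapply(use, genotype, character(1))
  small <- names(which(table(gt) < 2))
  if (length(small))
    warning("genotype(s) with < 2 crops excluded from ANOVA: ",
            paste(small, collapse = ", "))

  counts <- vector("list", length(grid))
  pvals <- numeric(length(grid))
  for (gi in seq_along(grid)) {
    s <- grid[gi]
    n <- numeric(length(use)); nper <- numeric(length(use))
    for (ci in seq_along(use)) {
      crop <- use[[ci]]
      ch <- channel(crop, channel)
      mask <- bradleyThreshold(ch, s, dpar@neighborhood)
      labels <- segmentROIs(mask, ch)
      if (max(labels) > 0) {
        tab <- measureROIs(labels, ch, pixelSize(crop))
        labels <- restrictROIs(labels, tab, rpar)$labels
      }
      n[ci] <- max(labels)
      nper[ci] <- countPer100um(n[ci], ncol(ch), pixelSize(crop))
    }
    counts[[gi]] <- data.frame(
      sensitivity = s,
      crop_id = vapply(use, cropId, character(1)),
      genotype = gt, n_rois = n, count_per_100um = nper
    )
    ok <- !(gt %in% small)
    pvals[gi] <- welch_anova_p(n[ok], gt[ok])
  }
  list(grid = grid, counts = do.call(rbind, counts),
       anova = data.frame(sensitivity = grid, p_value = pvals))
}

# Welch's one-way ANOVA p-value; 1 when all group means coincide (zero
# F statistic), NA when it cannot be computed (e.g., all-zero variances
# with differing means are still fine for oneway.test, but < 2 groups not)
welch_anova_p <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) return(NA_real_)
  means <- tapply(values, groups, mean)
  if (max(means) == min(means)) return(1)
  vars <- tapply(values, groups, stats::var)
  if (all(vars == 0)) return(0)  # separated point masses: unbounded statistic
  p <- tryCatch(
    stats::oneway.test(values ~ groups, var.equal = FALSE)$p.value,
    error = function(e) NaN
  )
  if (!is.finite(p)) {
    # Welch weights blow up when one group has zero variance; fall back to
    # the pooled-variance ANOVA, which is defined whenever any group varies
    p <- tryCatch(
      stats::oneway.test(values ~ groups, var.equal = TRUE)$p.value,
      error = function(e) NA_real_
    )
  }
  p
}

#' Pairwise Welch comparisons after a sweep
#'
#' Convenience glue for per-pair follow-up at one grid point: Welch t-tests
#' for every genotype pair with Holm adjustment (the multiple-comparison
#' step is delegated to standard routines, as is usual for this kind of
#' analysis).
#'
#' @param values numeric outcomes (e.g., ROI counts).
#' @param groups genotype labels.
#' @return `data.frame` with `group1`, `group2`, `p_value`, `p_adjusted`.
#' @export
pairwiseWelch <- function(values, groups) {
  groups <- factor(groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  p <- apply(pairs, 2, function(pr) {
    stats::t.test(values[groups == pr[1]], values[groups == pr[2]],
                  var.equal = FALSE)$p.value
  })
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
             p_value = p, p_adjusted = stats::p.adjust(p, "holm"))
}
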