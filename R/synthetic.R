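# run code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic straightened-crop scene with known ground truth
#'
#' Emulates a straightened nerve-cord crop: a thin strip (default 20 x 500
#' px, matching the 20-pixel line width used when tracing crops) with
#' isotropic Gaussian puncta laid out along the mid-line of the strip over a
#' uniform background, plus Gaussian read noise. Optional "edge confounders"
#' mimic autofluorescent gut granules: bright off-axis blobs placed within 3
#' px of the top/bottom (y) edges that appear in the image but not in the
#' ground truth.
#'
#' The ground-truth label of punctum k is the set of pixels where its
#' noiseless contribution reaches at least half its amplitude (the
#' half-maximum footprint); where footprints would overlap, the larger
#' contribution wins. Identical seeds give bit-identical scenes.
#'
#' @param height,width scene shape in pixels.
#' @param nPuncta number of puncta (>= 0).
#' @param amplitudeRange range of peak amplitudes (drawn uniformly).
#' @param sigmaRange range of Gaussian sigmas in px.
#' @param minSeparation minimum Euclidean distance between punctum centers,
#'   px; an infeasible packing raises an error.
#' @param background constant background offset.
#' @param readNoiseSd standard deviation of additive Gaussian read noise
#'   (the image is clipped at 0).
#' @param edgeConfounders number of gut-granule-like bright blobs near the
#'   y-edges.
#' @param pixelSize micrometers per pixel for the resulting crop.
#' @param genotype,cropId metadata for the resulting crop.
#' @param seed integer seed; `NULL` uses (and advances) the current RNG.
#' @return list with `crop` (a one-channel [CropImage-class]), `truth`
#'   (integer label matrix, one label per punctum) and `puncta` (a
#'   `data.frame` of centers, amplitudes and sigmas).
#' @examples
#' sc <- generateScene(nPuncta = 5, width = 120, seed = 1)
#' max(sc$truth)  # 5
#' @export
generateScene <- function(height = 20, width = 500, nPuncta = 12,
                          amplitudeRange = c(0.5, 1), sigmaRange = c(1.5, 2.5),
                          minSeparation = 12, background = 0.1,
                          readNoiseSd = 0.02, edgeConfounders = 0,
                          pixelSize = 0.21, genotype = "synthetic",
                          cropId = "scene", seed = NULL) {
  stopifnot(height >= 1, width >= 1, nPuncta >= 0, minSeparation >= 0,
            background >= 0, readNoiseSd >= 0, edgeConfounders >= 0,
            all(is.finite(c(amplitudeRange, sigmaRange))),
            all(amplitudeRange >= 0), all(sigmaRange > 0))
  with_seed(seed, {
    img <- matrix(background, height, width)
    contrib <- matrix(0, height, width)   # best noiseless contribution so far
    truth <- matrix(0L, height, width)

    # place centers along the cord mid-line band
    xmargin <- min(ceiling(3 * max(sigmaRange)), floor(width / 2))
    ymid <- (height + 1) / 2
    yjit <- min(2, (height - 1) / 2)
    centers <- matrix(numeric(0), 0, 2)
    tries <- 0L
    while (nrow(centers) < nPuncta) {
      if (tries > 200L * max(1L, nPuncta))
        stop("cannot place ", nPuncta, " puncta with minSeparation = ",
             minSeparation, " in a ", height, " x ", width, " scene")
      tries <- tries + 1L
      cand <- c(stats::runif(1, ymid - yjit, ymid + yjit),
                stats::runif(1, 1 + xmargin, width - xmargin))
      if (nrow(centers) == 0 ||
          all(sqrt(rowSums(sweep(centers, 2, cand)^2)) >= minSeparation))
        centers <- rbind(centers, cand)
    }

    amp <- if (nPuncta > 0)
      stats::runif(nPuncta, amplitudeRange[1], amplitudeRange[2]) else numeric()
    sig <- if (nPuncta > 0)
      stats::runif(nPuncta, sigmaRange[1], sigmaRange[2]) else numeric()

    add_blob <- function(img, cy, cx, a, s) {
      r0 <- max(1L, floor(cy - 4 * s)); r1 <- min(height, ceiling(cy + 4 * s))
      c0 <- max(1L, floor(cx - 4 * s)); c1 <- min(width, ceiling(cx + 4 * s))
      rr <- r0:r1; cc <- c0:c1
      g <- a * exp(-(outer((rr - cy)^2, (cc - cx)^2, "+")) / (2 * s^2))
      img[rr, cc] <- img[rr, cc] + g
      list(img = img, rows = rr, cols = cc, g = g)
    }

    for (k in seq_len(nPuncta)) {
      b <- add_blob(img, centers[k, 1], centers[k, 2], amp[k], sig[k])
      img <- b$img
      fp <- b$g >= amp[k] / 2 & b$g > contrib[b$rows, b$cols]
      sub_t <- truth[b$rows, b$cols]; sub_c <- contrib[b$rows, b$cols]
      sub_t[fp] <- k
      sub_c[fp] <- b$g[fp]
      truth[b$rows, b$cols] <- sub_t
      contrib[b$rows, b$cols] <- sub_c
    }

    # gut-granule mimics: bright, off-axis, absent from the truth
    for (k in seq_len(edgeConfounders)) {
      side <- stats::runif(1) < 0.5
      cy <- if (side) stats::runif(1, 1, min(3, height))
            else stats::runif(1, max(1, height - 2), height)
      cx <- stats::runif(1, 3, width - 2)
      img <- add_blob(img, cy, cx, 1.5 * max(amplitudeRange, 0.5), 1.5)$img
    }

    if (readNoiseSd > 0)
      img <- img + matrix(stats::rnorm(height * width, 0, readNoiseSd),
                          height, width)
    img <- pmax(img, 0)

    puncta <- data.frame(
      label = seq_len(nPuncta),
      row = if (nPuncta) centers[, 1] else numeric(),
      col = if (nPuncta) centers[, 2] else numeric(),
      amplitude = amp, sigma = sig
    )
    list(
      crop = CropImage(img, pixelSize = pixelSize, genotype = genotype,
                       cropId = cropId),
      truth = truth,
      puncta = puncta
    )
  })
}

#' Generate a multi-genotype synthetic dataset
#'
#' Builds a [CropDataset-class] of synthetic scenes, one group of crops per
#' genotype, with per-genotype scene settings. Seeds for individual scenes
#' are derived deterministically from `seed`.
#'
#' @param genotypeSpecs named list; each element is a list of
#'   [generateScene()] arguments (without `genotype`, `cropId`, `seed`).
#' @param nCrops crops per genotype (recycled).
#' @param seed integer seed for the whole dataset.
#' @param ... common [generateScene()] arguments applied to all genotypes.
#' @return list with `dataset` (a [CropDataset-class]) and `truths` (named
#'   list of ground-truth label maps, by cropId).
#' @export
generateSceneDataset <- function(genotypeSpecs, nCrops = 10, seed = 1, ...) {
  common <- list(...)
  nCrops <- rep_len(nCrops, length(genotypeSpecs))
  crops <- list(); truths <- list()
  counter <- 0L
  for (gi in seq_along(genotypeSpecs)) {
    gname <- names(genotypeSpecs)[gi]
    for (ci in seq_len(nCrops[gi])) {
      counter <- counter + 1L
      id <- sprintf("%s_%03d", gname, ci)
      args <- utils::modifyList(common, genotypeSpecs[[gi]])
      args$genotype <- gname
      args$cropId <- id
      args$seed <- (seed * 10000L + counter) %% .Machine$integer.max
      sc <- do.call(generateScene, args)
      crops[[counter]] <- sc$crop
      truths[[id]] <- sc$truth
    }
  }
  list(dataset = CropDataset(crops), truths = truths)
}

#' Add microscopy noise to an image
#'
#' Injects one of four classic noise models. The image is min-max rescaled
#' to \[0, 1\] internally, the noise is applied on that scale, the result is
#' clipped to \[0, 1\] and mapped back to the original intensity range (the
#' usual convention of image-noise utilities).
#'
#' \describe{
#'   \item{gaussian}{adds N(`mean`, `variance`) to every pixel (thermal
#'     noise).}
#'   \item{poisson}{replaces each pixel by a Poisson draw with mean equal to
#'     the pixel value on a counts scale (`poissonScale` counts at
#'     intensity 1), divided back (shot noise).}
#'   \item{speckle}{multiplicative: I * (1 + U) with zero-mean uniform U of
#'     the given `variance`.}
#'   \item{salt_pepper}{each pixel is replaced with probability `density`,
#'     half going to 0 and half to 1 (impulse noise; density 0.05 replaces
#'     ~5\% of pixels).}
#' }
#'
#' Grids used in robustness studies keep `mean` and `variance` within
#' \[0, 0.2\] and `density` within \[0, 0.05\]; values outside these ranges
#' are rejected.
#'
#' @param image numeric matrix.
#' @param kind one of `"poisson"`, `"gaussian"`, `"speckle"`,
#'   `"salt_pepper"`.
#' @param mean,variance Gaussian parameters (variance also for speckle).
#' @param density salt-and-pepper replacement fraction.
#' @param poissonScale counts corresponding to intensity 1 on the
#'   normalized scale.
#' @param seed integer seed; `NULL` uses the current RNG.
#' @return noisy matrix on the original intensity scale.
#' @examples
#' img <- matrix(runif(100), 10, 10)
#' identical(addNoise(img, "gaussian", mean = 0, variance = 0), img)
#' @export
addNoise <- function(image, kind = c("gaussian", "poisson", "speckle",
                                     "salt_pepper"),
                     mean = 0, variance = 0.01, density = 0.05,
                     poissonScale = 1000, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (kind == "gaussian" && (mean < 0 || mean > 0.2 ||
                             variance < 0 || variance > 0.2))
    stop("gaussian mean and variance must lie in [0, 0.2]")
  if (kind == "speckle" && (variance < 0 || variance > 0.2))
    stop("speckle variance must lie in [0, 0.2]")
  if (kind == "salt_pepper" && (density < 0 || density > 0.05))
    stop("salt_pepper density must lie in [0, 0.05]")
  lo <- min(image); hi <- max(image)
  scale <- if (hi > lo) hi - lo else 1
  x <- (image - lo) / scale
  n <- length(x)
  with_seed(seed, {
    y <- switch(kind,
      gaussian = x + stats::rnorm(n, mean, sqrt(variance)),
      poisson = stats::rpois(n, lambda = as.vector(x) * poissonScale) /
        poissonScale,
      speckle = {
        a <- sqrt(3 * variance)
        x * (1 + stats::runif(n, -a, a))
      },
      salt_pepper = {
        y <- as.vector(x)
        hit <- stats::runif(n) < density
        y[hit] <- ifelse(stats::runif(sum(hit)) < 0.5, 0, 1)
        y
      }
    )
    y <- matrix(pmin(pmax(y, 0), 1), nrow(image), ncol(image))
    y * scale + lo
  })
}

#' Noise robustness study of the colocalization metrics
#'
#' For each noise setting in `grid`, builds a synthetic second channel by
#' applying the noise to channel 1 of every crop, runs the fixed detection
#' pipeline on both, and computes normalized PCC (on the raw intensities of
#' original vs. noisy image), binary M1 (on the restricted masks) and R1 at
#' `theta` (original-channel ROIs against the noisy channel's restricted
#' support). Metric failures are recorded as missing values.
#'
#' @param crops list of one-channel [CropImage-class] objects (or a
#'   [CropDataset-class]; excluded crops are skipped).
#' @param config an [AnalysisConfig-class] (channel-1 settings are used for
#'   both images).
#' @param grid `data.frame` with columns `kind` and, as applicable, `mean`,
#'   `variance`, `density`. See [noiseGrid()] for the standard grids.
#' @param theta overlap threshold for R1.
#' @param seed integer seed; per-crop noise seeds are derived from it.
#' @return list with `perCrop` (long `data.frame`) and `summary` (mean and
#'   SD of each metric per grid row).
#' @export
noiseStudy <- function(crops, config, grid = noiseGrid(), theta = 0.3,
                       seed = 1) {
  if (is(crops, "CropDataset")) crops <- activeCrops(crops)
  stopifnot(is(config, "AnalysisConfig"))
  dpar <- config@detection[[1]]
  rpar <- config@restriction[[1]]
  analyze <- function(ch) {
    det <- detectROIs(ch, dpar)
    labels <- det$labels
    if (max(labels) > 0) {
      tab <- measureROIs(labels, ch, config@pixelSize)
      labels <- restrictROIs(labels, tab, rpar)$labels
    }
    labels
  }
  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    g <- grid[gi, ]
    for (ci in seq_along(crops)) {
      ch1 <- channel(crops[[ci]], 1L)
      nseed <- (seed * 100003L + gi * 1009L + ci) %% .Machine$integer.max
      ch2 <- addNoise(ch1, kind = as.character(g$kind),
                      mean = g$mean %||% 0, variance = g$variance %||% 0,
                      density = g$density %||% 0, seed = nseed)
      vals <- tryCatch({
        l1 <- analyze(ch1); l2 <- analyze(ch2)
        m <- manders(l1 > 0, l2 > 0)
        c(pcc_normalized = pccNormalized(ch1, ch2),
          m1 = unname(m["m1"]),
          r1 = roiOverlapRatio(l1, l2 > 0, theta))
      }, error = function(e) {
        warning("crop ", cropId(crops[[ci]]), " @ grid row ", gi, ": ",
                conditionMessage(e), call. = FALSE)
        c(pcc_normalized = NA_real_, m1 = NA_real_, r1 = NA_real_)
      })
      rows[[length(rows) + 1L]] <- data.frame(
        grid_row = gi, kind = as.character(g$kind),
        mean = g$mean %||% NA_real_, variance = g$variance %||% NA_real_,
        density = g$density %||% NA_real_,
        crop_id = cropId(crops[[ci]]),
        pcc_normalized = vals[["pcc_normalized"]],
        m1 = vals[["m1"]], r1 = vals[["r1"]]
      )
    }
  }
  perCrop <- do.call(rbind, rows)
  sp <- split(perCrop, perCrop$grid_row)
  summary <- do.call(rbind, lapply(sp, function(d) {
    data.frame(
      grid_row = d$grid_row[1], kind = d$kind[1], mean = d$mean[1],
      variance = d$variance[1], density = d$density[1],
      pcc_normalized_mean = mean(d$pcc_normalized, na.rm = TRUE),
      pcc_normalized_sd = stats::sd(d$pcc_normalized, na.rm = TRUE),
      m1_mean = mean(d$m1, na.rm = TRUE), m1_sd = stats::sd(d$m1, na.rm = TRUE),
      r1_mean = mean(d$r1, na.rm = TRUE), r1_sd = stats::sd(d$r1, na.rm = TRUE)
    )
  }))
  rownames(summary) <- NULL
  list(perCrop = perCrop, summary = summary)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Standard noise parameter grids
#'
#' The grids conventionally used for the four noise models: Gaussian mean
#' varied over 0-0.2 at variance 0.01, Gaussian variance over 0-0.2 at mean
#' 0, speckle variance over 0-0.2, and salt-and-pepper density over 0-0.05.
#'
#' @param nStep number of grid points per varied parameter.
#' @return `data.frame` suitable for [noiseStudy()].
#' @export
noiseGrid <- function(nStep = 5) {
  gm <- seq(0, 0.2, length.out = nStep)
  gv <- seq(0, 0.2, length.out = nStep)
  sv <- seq(0, 0.2, length.out = nStep)
  dd <- seq(0, 0.05, length.out = nStep)
  rbind(
    data.frame(kind = "gaussian", mean = gm, variance = 0.01, density = NA),
    data.frame(kind = "gaussian", mean = 0, variance = gv, density = NA),
    data.frame(kind = "speckle", mean = NA, variance = sv, density = NA),
    data.frame(kind = "salt_pepper", mean = NA, variance = NA, density = dd),
    data.frame(kind = "poisson", mean = NA, variance = NA, density = NA)
  )
}
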