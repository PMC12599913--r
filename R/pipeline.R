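#' Run the full analysis pipeline over a dataset
#'
#' Executes the batch pipeline, per crop and channel: threshold -> watershed
#' segmentation -> restriction -> measurement, and, for two-channel crops,
#' the colocalization metrics at the configured overlap threshold. Excluded
#' crops are skipped but logged in the manifest. The run is deterministic:
#' the same dataset and config reproduce bit-identical tables and label
#' maps.
#'
#' @param dataset a [CropDataset-class].
#' @param config an [AnalysisConfig-class].
#' @param outDir optional output directory; when given, writes
#'   `combined_rois.csv` (one row per ROI), `crop_summary.csv` (one row per
#'   crop and channel), `colocalization.csv` (one row per two-channel crop),
#'   and `manifest.json`.
#' @return (invisibly when writing) a list with `rois`, `summary`, `coloc`
#'   data frames, `labels` (named list: per crop, per channel restricted
#'   label maps) and `manifest`.
#' @examples
#' sc <- generateScene(nPuncta = 6, width = 150, seed = 7)
#' ds <- CropDataset(list(sc$crop))
#' res <- runPipeline(ds, AnalysisConfig(pixelSize = 0.21))
#' res$summary
#' @export
runPipeline <- function(dataset, config, outDir = NULL) {
  stopifnot(is(dataset, "CropDataset"), is(config, "AnalysisConfig"))
  validObject(dataset); validObject(config)

  roi_rows <- list(); sum_rows <- list(); coloc_rows <- list()
  labels_out <- list()
  status <- character(length(dataset))
  ids <- cropIds(dataset)
  names(status) <- ids

  for (ci in seq_len(length(dataset))) {
    crop <- dataset@crops[[ci]]
    id <- cropId(crop)
    if (id %in% excludedIds(dataset)) {
      status[id] <- "excluded"
      next
    }
    res <- tryCatch({
      nch <- min(nChannels(crop), length(config@detection))
      per_channel <- vector("list", nch)
      for (k in seq_len(nch)) {
        ch <- channel(crop, k)
        det <- detectROIs(ch, config@detection[[k]])
        labels <- det$labels
        tab <- measureROIs(labels, ch, pixelSize(crop))
        if (nrow(tab)) {
          r <- restrictROIs(labels, tab, config@restriction[[k]])
          labels <- r$labels; tab <- r$table
        } else {
          tab$original_label <- integer()
        }
        per_channel[[k]] <- list(labels = labels, table = tab, mask = det$mask)
      }
      per_channel
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[id] <- paste0("error: ", conditionMessage(res))
      warning("crop ", id, " failed: ", conditionMessage(res), call. = FALSE)
      next
    }
    status[id] <- "ok"
    labels_out[[id]] <- lapply(res, `[[`, "labels")

    for (k in seq_along(res)) {
      tab <- res[[k]]$table
      labels <- res[[k]]$labels
      chm <- channel(crop, k)
      if (nrow(tab)) {
        roi_rows[[length(roi_rows) + 1L]] <- cbind(
          data.frame(crop_id = id, genotype = genotype(crop),
                     channel = config@channelNames[k]),
          tab
        )
      }
      n <- max(labels)
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        crop_id = id, genotype = genotype(crop),
        channel = config@channelNames[k],
        n_rois = n,
        count_per_100um = countPer100um(n, ncol(chm), pixelSize(crop)),
        snr = if (any(labels > 0) && sum(chm[labels == 0]) > 0)
          snr(chm, labels > 0) else NA_real_,
        mean_roi_intensity = if (n > 0) mean(chm[labels > 0]) else NA_real_
      )
    }
    if (length(res) == 2L) {
      cl <- tryCatch(
        colocalizeCrop(channel(crop, 1L), channel(crop, 2L),
                       res[[1]]$labels, res[[2]]$labels,
                       theta = config@overlapThreshold),
        error = function(e) {
          warning("colocalization failed for crop ", id, ": ",
                  conditionMessage(e), call. = FALSE)
          NULL
        }
      )
      if (!is.null(cl))
        coloc_rows[[length(coloc_rows) + 1L]] <-
          cbind(data.frame(crop_id = id, genotype = genotype(crop)), cl)
    }
  }

  empty_df <- function() data.frame()
  out <- list(
    rois = if (length(roi_rows)) do.call(rbind, roi_rows) else empty_df(),
    summary = if (length(sum_rows)) do.call(rbind, sum_rows) else empty_df(),
    coloc = if (length(coloc_rows)) do.call(rbind, coloc_rows) else empty_df(),
    labels = labels_out,
    manifest = list(
      tool = "punctakit",
      version = as.character(utils::packageVersion("punctakit")),
      config = config_as_list(config),
      inputs = lapply(seq_len(length(dataset)), function(i) {
        crop <- dataset@crops[[i]]
        list(crop_id = cropId(crop), genotype = genotype(crop),
             shape = dim(crop), channels = nChannels(crop),
             checksum = crop_checksum(crop),
             status = unname(status[cropId(crop)]))
      })
    )
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$rois, file.path(outDir, "combined_rois.csv"),
                     row.names = FALSE)
    utils::write.csv(out$summary, file.path(outDir, "crop_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(out$coloc, file.path(outDir, "colocalization.csv"),
                     row.names = FALSE)
    jsonlite::write_json(out$manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    return(invisible(out))
  }
  out
}

# content checksum of a crop's pixel data (md5 of the serialized channels)
crop_checksum <- function(crop) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(channels(crop), f, version = 2)
  unname(tools::md5sum(f))
}

# boundary pixels of each labeled region (pixels with a 4-neighbor of a
# different label or the border)
label_outlines <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2L, nc + 2L)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- labels
  b <- array(FALSE, dim(labels))
  for (sh in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nb <- pad[2:(nr + 1) + sh[1], 2:(nc + 1) + sh[2]]
    b <- b | (core > 0 & nb != core)
  }
  b
}

#' Render a crop with ROI outlines
#'
#' Writes a PNG of the grayscale intensities with ROI outlines drawn on
#' top: channel-1 ROIs in green and (optionally) channel-2 ROIs in magenta,
#' the usual two-channel display convention.
#'
#' @param crop a [CropImage-class].
#' @param labels1 label map drawn in green (may be `NULL`).
#' @param labels2 optional label map drawn in magenta.
#' @param file output PNG path.
#' @param channel which channel's intensities form the grayscale base.
#' @return `file`, invisibly.
#' @export
renderOverlay <- function(crop, labels1, labels2 = NULL, file,
                          channel = 1L) {
  ch <- channel(crop, channel)
  base <- normalizeImage(ch)
  rgb <- array(rep(base, 3), dim = c(dim(base), 3))
  if (!is.null(labels1)) {
    if (!identical(dim(labels1), dim(ch))) stop("labels1 shape mismatch")
    o <- label_outlines(labels1)
    rgb[, , 1][o] <- 0; rgb[, , 2][o] <- 1; rgb[, , 3][o] <- 0
  }
  if (!is.null(labels2)) {
    if (!identical(dim(labels2), dim(ch))) stop("labels2 shape mismatch")
    o <- label_outlines(labels2)
    rgb[, , 1][o] <- 1; rgb[, , 2][o] <- 0; rgb[, , 3][o] <- 1
  }
  png::writePNG(rgb, file)
  invisible(file)
}

#' Render a montage of crops
#'
#' Tiles crops (grayscale, with optional green outlines) top-to-bottom in
#' dataset order, separated by thin white gutters, and draws a scale bar of
#' `scaleBarUm` micrometers in the bottom-right corner.
#'
#' @param cropsList list of [CropImage-class] objects.
#' @param labelsList optional list of label maps (same length).
#' @param file output PNG path.
#' @param scaleBarUm scale bar length in micrometers (0 disables).
#' @param channel channel index used for the grayscale base.
#' @return `file`, invisibly.
#' @export
renderMontage <- function(cropsList, labelsList = NULL, file,
                          scaleBarUm = 5, channel = 1L) {
  stopifnot(length(cropsList) >= 1)
  gutter <- 2L
  widths <- vapply(cropsList, function(cr) ncol(channel(cr, channel)), 1L)
  W <- max(widths)
  tiles <- lapply(seq_along(cropsList), function(i) {
    cr <- cropsList[[i]]
    base <- normalizeImage(channel(cr, channel))
    rgb <- array(rep(base, 3), dim = c(dim(base), 3))
    if (!is.null(labelsList) && !is.null(labelsList[[i]])) {
      o <- label_outlines(labelsList[[i]])
      rgb[, , 1][o] <- 0; rgb[, , 2][o] <- 1; rgb[, , 3][o] <- 0
    }
    if (ncol(base) < W) {   # pad to common width
      padded <- array(0, dim = c(nrow(base), W, 3))
      padded[, seq_len(ncol(base)), ] <- rgb
      rgb <- padded
    }
    rgb
  })
  H <- sum(vapply(tiles, function(t) dim(t)[1], 1L)) +
    gutter * (length(tiles) - 1L)
  canvas <- array(1, dim = c(H, W, 3))
  r <- 1L
  for (t in tiles) {
    h <- dim(t)[1]
    canvas[r:(r + h - 1L), , ] <- t
    r <- r + h + gutter
  }
  if (scaleBarUm > 0) {
    px <- round(scaleBarUm / pixelSize(cropsList[[1]]))
    px <- min(px, W - 2L)
    if (px >= 2) {
      canvas[(H - 1L):H, (W - px):(W - 1L), 1] <- 1
      canvas[(H - 1L):H, (W - px):(W - 1L), 2] <- 1
      canvas[(H - 1L):H, (W - px):(W - 1L), 3] <- 0
    }
  }
  png::writePNG(canvas, file)
  invisible(file)
}
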