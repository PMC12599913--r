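test_that("confusion rates match hand-counted contingency tables", {
  truth <- matrix(FALSE, 4, 4); truth[1, 1:4] <- TRUE  # P = 4, N = 12
  pred <- matrix(FALSE, 4, 4)
  pred[1, 1:2] <- TRUE      # TP = 2, FN = 2
  pred[2, 1:2] <- TRUE      # FP = 2, TN = 10
  cr <- confusionRates(pred, truth)
  expect_equal(cr$tpr, 0.5)
  expect_equal(cr$tnr, 10 / 12)
  expect_equal(cr$balanced_accuracy, (0.5 + 10 / 12) / 2)

  mixed <- matrix(c(TRUE, FALSE), 4, 4)
  self <- confusionRates(mixed, mixed)
  expect_equal(unlist(self[1:3]), c(tpr = 1, tnr = 1, balanced_accuracy = 1))
  comp <- confusionRates(!mixed, mixed)
  expect_equal(unlist(comp[1:3]), c(tpr = 0, tnr = 0, balanced_accuracy = 0))

  expect_error(confusionRates(mixed, matrix(FALSE, 4, 4)), "TPR undefined")
  expect_error(confusionRates(mixed, matrix(TRUE, 4, 4)), "TNR undefined")
})

test_that("balanced accuracy is exactly the TPR/TNR mean on random masks", {
  set.seed(17)
  for (rep in 1:20) {
    truth <- matrix(runif(300) < 0.3, 15, 20)
    pred <- matrix(runif(300) < 0.4, 15, 20)
    if (!any(truth) || all(truth)) next
    for (mode in c("pixel2d", "column1d")) {
      cr <- tryCatch(confusionRates(pred, truth, mode), error = function(e) NULL)
      if (is.null(cr)) next
      expect_identical(cr$balanced_accuracy, (cr$tpr + cr$tnr) / 2)
    }
  }
})

test_that("column mode equals pixel mode on the collapsed masks", {
  set.seed(23)
  pred <- matrix(runif(200) < 0.2, 10, 20)
  truth <- matrix(runif(200) < 0.2, 10, 20)
  collapse <- function(m) matrix(colSums(m) > 0, 1)
  a <- confusionRates(pred, truth, "column1d")
  b <- confusionRates(collapse(pred), collapse(truth), "pixel2d")
  expect_equal(a[c("tpr", "tnr", "balanced_accuracy")],
               b[c("tpr", "tnr", "balanced_accuracy")])
})

test_that("profile peaks: apex detection, valley separation, filters", {
  # single triangular bump on a flat baseline
  prof <- c(rep(1, 10), 1 + 1:5, 1 + 4:0, rep(1, 10))
  img <- matrix(prof, nrow = 1)
  pk <- findProfilePeaks(img)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$position, 15L)
  expect_equal(pk$height, 6)

  # two bumps separated by a valley deeper than the prominence floor
  prof2 <- c(rep(1, 5), 1 + c(1, 3, 5, 3, 2), 1 + c(3, 5, 3, 1), rep(1, 5))
  pk2 <- findProfilePeaks(matrix(prof2, nrow = 1), minProminence = 2)
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$position, c(8L, 12L))

  # a bump below the noise-to-signal height floor is excluded
  prof3 <- c(rep(10, 8), 10 + 1:3, 10 + 2:0, rep(10, 8))
  expect_equal(nrow(findProfilePeaks(matrix(prof3, nrow = 1),
                                     noiseToSignalRatio = 2)), 0L)
  expect_equal(nrow(findProfilePeaks(matrix(prof3, nrow = 1),
                                     noiseToSignalRatio = 1)), 1L)

  # flat profile: no peaks
  expect_equal(nrow(findProfilePeaks(matrix(5, 3, 30))), 0L)

  # every reported peak is a strict local maximum of the profile (oracle)
  sc <- generateScene(nPuncta = 6, width = 200, seed = 31)
  ch <- channel(sc$crop)
  prof <- colSums(ch)
  pk <- findProfilePeaks(ch, minProminence = 0.5)
  for (p in pk$position)
    expect_true(prof[p] >= max(prof[max(1, p - 1)], prof[min(length(prof), p + 1)]))
})

test_that("peak claims convert to a column mask aligned with ground truth", {
  sc <- generateScene(nPuncta = 5, width = 200, minSeparation = 25,
                      readNoiseSd = 0.005, seed = 41)
  ch <- channel(sc$crop)
  pk <- findProfilePeaks(ch, minProminence = 1)
  mask <- peaksToMask(pk, ncol(ch))
  expect_equal(dim(mask), c(1L, ncol(ch)))
  cr <- confusionRates(peaksToMask(pk, ncol(ch), height = nrow(ch)),
                       sc$truth > 0, mode = "column1d")
  expect_gt(cr$tpr, 0.8)  # peaks land on true puncta columns
})

test_that("the sensitivity grid spans optimum +/- 0.15 in 0.01 steps", {
  ds <- generateSceneDataset(
    list(a = list(nPuncta = 4), b = list(nPuncta = 4)),
    nCrops = 2, seed = 1, width = 100
  )
  cfg <- AnalysisConfig(detection = DetectionParams(sensitivity = 0.2),
                        restriction = RestrictionParams(minArea = 5))
  sw <- sensitivitySweep(ds$dataset, cfg)
  expect_equal(length(sw$grid), 31L)
  expect_equal(sw$grid[1], 0.05)
  expect_equal(sw$grid[31], 0.35)
  expect_equal(sw$anova$sensitivity, sw$grid)
})

test_that("identical genotype groups never separate (p = 1)", {
  scs <- lapply(1:4, function(i)
    generateScene(nPuncta = 6, width = 120, seed = 100 + i,
                  cropId = sprintf("c%d", i)))
  crops <- list()
  for (i in 1:4) {
    a <- scs[[i]]$crop
    crops[[i]] <- CropImage(channels(a), 0.21, genotype = "g1",
                            cropId = paste0("a", i))
    crops[[i + 4]] <- CropImage(channels(a), 0.21, genotype = "g2",
                                cropId = paste0("b", i))
  }
  ds <- CropDataset(crops)
  cfg <- tuned_config()
  sw <- sensitivitySweep(ds, cfg, halfRange = 0.05, step = 0.05)
  expect_true(all(sw$anova$p_value >= 0.999))
})

test_that("genotypes with one crop are dropped from the ANOVA with a warning", {
  ds <- generateSceneDataset(
    list(a = list(nPuncta = 8), b = list(nPuncta = 3), c = list(nPuncta = 8)),
    nCrops = c(3, 3, 1), seed = 2, width = 220
  )
  expect_warning(
    sw <- sensitivitySweep(ds$dataset, tuned_config(), halfRange = 0.01,
                           step = 0.01),
    "excluded from ANOVA"
  )
  expect_true(all(is.finite(sw$anova$p_value)))
})

test_that("pairwise Welch comparisons cover all genotype pairs", {
  set.seed(5)
  v <- c(rnorm(6, 10), rnorm(6, 3), rnorm(6, 10))
  g <- rep(c("ctl", "sev", "mild"), each = 6)
  pw <- pairwiseWelch(v, g)
  expect_equal(nrow(pw), 3L)
  expect_true(all(pw$p_adjusted >= pw$p_value - 1e-15))
})
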