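test_that("per-ROI measurements follow the documented conventions", {
  lab <- matrix(0L, 10, 20)
  lab[3:4, 3:5] <- 1L   # 2x3 block, 6 px
  lab[8, 10] <- 2L      # single pixel
  ch <- matrix(1, 10, 20); ch[3, 3] <- 7
  tab <- measureROIs(lab, ch, pixelSize = 0.21)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$area_px2, c(6L, 1L))
  expect_equal(tab$area_um2, c(6, 1) * 0.21^2)
  expect_equal(tab$sum_intensity, c(12, 1))
  expect_equal(tab$max_intensity, c(7, 1))
  # single-pixel conventions
  expect_equal(tab$circularity[2], 1)
  expect_equal(tab$length_width_ratio[2], 1)
  expect_equal(tab$intensity_variance[2], 0)
  # 5 px at 0.21 um/px -> 0.2205 um^2 (the usual minimum-area setting)
  lab5 <- matrix(0L, 5, 5); lab5[2:3, 2:3] <- 1L; lab5[4, 2] <- 1L
  t5 <- measureROIs(lab5, matrix(1, 5, 5), 0.21)
  expect_equal(t5$area_um2, 0.2205)
})

test_that("length-width ratio matches the closed-form bar moments", {
  # a 1 x n bar has coordinate variance (n^2-1)/12; with the 1/12 pixel term
  # the moment ellipse axis ratio is exactly n
  for (n in c(2, 5, 10)) {
    lab <- matrix(0L, 5, n + 4)
    lab[3, 3:(n + 2)] <- 1L
    tab <- measureROIs(lab, matrix(1, 5, n + 4), 1)
    expect_equal(tab$length_width_ratio, n)
  }
  # a diagonal line: eigenvalues from the hand-built covariance matrix
  lab <- matrix(0L, 8, 8); for (i in 1:5) lab[i + 1, i + 1] <- 1L
  tab <- measureROIs(lab, matrix(1, 8, 8), 1)
  v <- mean((1:5 - 3)^2)
  C <- matrix(c(v + 1 / 12, v, v, v + 1 / 12), 2)
  ev <- eigen(C)$values
  expect_equal(tab$length_width_ratio, sqrt(ev[1] / ev[2]))
})

test_that("gapped label maps are rejected", {
  lab <- matrix(0L, 4, 4); lab[1, 1] <- 1L; lab[3, 3] <- 3L
  expect_error(measureROIs(lab, matrix(1, 4, 4), 1), "contiguous")
})

test_that("edge exclusion removes border-touching ROIs only when enabled", {
  # an off-axis blob touching the bottom edge (gut-granule geometry) plus a
  # well-centered punctum
  lab <- matrix(0L, 20, 60)
  lab[18:20, 10:13] <- 1L   # touches bottom rows
  lab[9:11, 30:32] <- 2L
  ch <- matrix(1, 20, 60)
  tab <- measureROIs(lab, ch, 0.21)
  res3 <- restrictROIs(lab, tab, RestrictionParams(yEdge = 3, minArea = NA))
  expect_equal(res3$removed, 1L)
  expect_equal(max(res3$labels), 1L)
  expect_equal(res3$table$original_label, 2L)
  res0 <- restrictROIs(lab, tab, RestrictionParams(yEdge = 0, minArea = NA))
  expect_equal(length(res0$removed), 0L)
  expect_equal(max(res0$labels), 2L)
})

test_that("the minimum-area filter removes few-pixel noise ROIs", {
  lab <- matrix(0L, 15, 40)
  lab[3, 5] <- 1L                  # 1 px
  lab[8, 10:12] <- 2L              # 3 px
  lab[10:11, 25:27] <- 3L          # 6 px
  tab <- measureROIs(lab, matrix(1, 15, 40), 0.21)
  res <- restrictROIs(lab, tab, RestrictionParams(minArea = 5))
  expect_equal(res$removed, c(1L, 2L))
  expect_equal(res$table$original_label, 3L)
})

test_that("restriction equals brute-force per-ROI predicate evaluation", {
  params <- RestrictionParams(xEdge = 2, yEdge = 2, minArea = 3, maxArea = 18,
                              minCircularity = 0.2, maxLengthWidthRatio = 4)
  for (seed in 1:40) {
    lab <- random_label_map(seed)
    if (max(lab) == 0) next
    ch <- matrix(runif(length(lab)), nrow(lab))
    tab <- measureROIs(lab, ch, 0.21)
    res <- restrictROIs(lab, tab, params)
    # oracle: evaluate every rule directly on each ROI's pixel set
    survive <- logical(nrow(tab))
    for (k in seq_len(nrow(tab))) {
      px <- which(lab == k, arr.ind = TRUE)
      in_margin <- any(px[, 1] <= 2 | px[, 1] > nrow(lab) - 2 |
                       px[, 2] <= 2 | px[, 2] > ncol(lab) - 2)
      a <- nrow(px)
      survive[k] <- !in_margin && a >= 3 && a <= 18 &&
        tab$circularity[k] >= 0.2 && tab$length_width_ratio[k] <= 4
    }
    expect_identical(sort(res$table$original_label), which(survive))
    # conservation: surviving pixel sets unchanged, only ids remapped
    for (i in seq_len(nrow(res$table)))
      expect_identical(res$labels == i,
                       lab == res$table$original_label[i])
  }
})

test_that("restriction is idempotent and monotone in each bound", {
  for (seed in 1:10) {
    lab <- random_label_map(seed)
    if (max(lab) == 0) next
    ch <- matrix(runif(length(lab)), nrow(lab))
    tab <- measureROIs(lab, ch, 0.21)
    p <- RestrictionParams(yEdge = 2, minArea = 4)
    r1 <- restrictROIs(lab, tab, p)
    t2 <- measureROIs(r1$labels, ch, 0.21)
    r2 <- restrictROIs(r1$labels, t2, p)
    expect_identical(r2$labels, r1$labels)
    expect_equal(length(r2$removed), 0L)
    # tightening an individual bound never increases survivors
    n_base <- nrow(restrictROIs(lab, tab, RestrictionParams(minArea = 3))$table)
    n_tight <- nrow(restrictROIs(lab, tab, RestrictionParams(minArea = 6))$table)
    expect_lte(n_tight, n_base)
  }
})

test_that("count normalization and SNR follow their definitions", {
  expect_equal(countPer100um(10, 500, 0.2), 10)
  expect_equal(countPer100um(0, 500, 0.2), 0)
  expect_equal(countPer100um(7, 476, 0.21), 7 / (476 * 0.21) * 100)
  expect_error(countPer100um(1, 0, 0.2), "length")

  ch <- matrix(1, 10, 10); mask <- matrix(FALSE, 10, 10)
  ch[, 1:5] <- 9; mask[, 1:5] <- TRUE
  expect_equal(snr(ch, mask), 9)
  expect_equal(snr(ch, matrix(FALSE, 10, 10)), 0)
  expect_error(snr(matrix(c(1, 0), 1), matrix(c(TRUE, FALSE), 1)),
               "undefined")
  # direct summation oracle on a generated scene
  sc <- generateScene(nPuncta = 6, width = 150, seed = 5)
  ch <- channel(sc$crop); m <- sc$truth > 0
  expect_equal(snr(ch, m), sum(ch[m]) / sum(ch[!m]))
})
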