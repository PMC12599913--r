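test_that("PCC identities: self-correlation, anticorrelation, affine invariance", {
  set.seed(2)
  x <- matrix(runif(200), 10, 20)
  expect_equal(pcc(x, x), 1, tolerance = 1e-12)
  expect_equal(pcc(x, -3 * x + 7), -1, tolerance = 1e-12)
  expect_equal(pcc(x, 2.5 * x + 1), 1, tolerance = 1e-12)
  y <- matrix(runif(200), 10, 20)
  expect_equal(pcc(2 * x + 3, 0.5 * y + 11), pcc(x, y), tolerance = 1e-12)
  expect_error(pcc(x, matrix(5, 10, 20)), "constant")
})

test_that("PCC equals the direct formula on a hand-evaluated case", {
  ch1 <- matrix(c(1, 2, 3, 4), 2, 2)
  ch2 <- matrix(c(1, 2, 2, 5), 2, 2)
  num <- sum((ch1 - mean(ch1)) * (ch2 - mean(ch2)))
  den <- sqrt(sum((ch1 - mean(ch1))^2) * sum((ch2 - mean(ch2))^2))
  expect_equal(pcc(ch1, ch2), num / den)
  expect_equal(pccNormalized(ch1, ch2), (num / den + 1) / 2)
})

test_that("binary Manders coefficients count overlap fractions", {
  a <- matrix(FALSE, 5, 8); a[2, 2:4] <- TRUE
  expect_equal(unname(manders(a, a)), c(1, 1))
  b <- matrix(FALSE, 5, 8); b[4, 2:4] <- TRUE
  expect_equal(unname(manders(a, b)), c(0, 0))
  # |m1| = 10, |m2| = 4, overlap 2
  m1 <- matrix(FALSE, 5, 8); m1[1:2, 1:5] <- TRUE
  m2 <- matrix(FALSE, 5, 8); m2[2, 4:7] <- TRUE
  expect_equal(unname(manders(m1, m2)), c(2 / 10, 2 / 4))
  # swap symmetry and subset
  expect_equal(unname(manders(m2, m1)), c(2 / 4, 2 / 10))
  sub <- matrix(FALSE, 5, 8); sub[1, 2:3] <- TRUE
  expect_equal(unname(manders(sub, m1)["m1"]), 1)
  expect_error(manders(matrix(FALSE, 2, 2), m1[1:2, 1:2]), "M1 undefined")
})

test_that("ROI overlap uses an inclusive threshold and never counts zero overlap", {
  lab <- matrix(0L, 5, 10); lab[2:3, 2:6] <- 1L  # one 10-px ROI
  other <- matrix(FALSE, 5, 10); other[2, 2:4] <- TRUE  # 3 px overlap
  expect_equal(roiOverlapRatio(lab, other, 0.3), 1)   # 0.3 <= 3/10
  expect_equal(roiOverlapRatio(lab, other, 0.31), 0)
  # zero-overlap ROI is not colocalized even at theta = 0
  expect_equal(roiOverlapRatio(lab, matrix(FALSE, 5, 10), 0), 0)
  expect_error(roiOverlapRatio(matrix(0L, 5, 10), other, 0.5), "no ROIs")
  # identical maps: both directions 1 at theta 0.5; disjoint maps 0
  lab2 <- matrix(0L, 5, 10); lab2[4:5, 8:9] <- 1L
  expect_equal(roiOverlapRatio(lab, lab > 0, 0.5), 1)
  expect_equal(roiOverlapRatio(lab, lab2 > 0, 0.05), 0)
})

test_that("overlap curves are monotone with exact endpoint semantics", {
  set.seed(9)
  # construct labels1 with known per-ROI coverage fractions in channel 2
  lab1 <- matrix(0L, 10, 50)
  lab1[2:3, 1:5] <- 1L; lab1[5:6, 11:15] <- 2L; lab1[8:9, 21:25] <- 3L
  mask2 <- matrix(FALSE, 10, 50)
  mask2[2:3, 1:5] <- TRUE          # ROI 1 fully covered
  mask2[5, 11:14] <- TRUE          # ROI 2: 4/10
  # ROI 3: no overlap
  thetas <- seq(0, 1, by = 0.1)
  r <- vapply(thetas, function(th) roiOverlapRatio(lab1, mask2, th), 1)
  expect_true(all(diff(r) <= 0))
  expect_equal(r[1], 2 / 3)        # theta 0: any-overlap fraction
  expect_equal(r[length(r)], 1 / 3)  # theta 1: fully covered fraction

  lab2 <- matrix(0L, 10, 50); lab2[mask2] <- 1L
  lab2 <- labelComponents(lab2 > 0)
  cur <- overlapCurve(list(list(labels1 = lab1, labels2 = lab2)),
                      thetas = c(0, 0.4, 0.41, 1))
  expect_equal(cur$perCrop$r1, c(2 / 3, 2 / 3, 1 / 3, 1 / 3))
})

test_that("a constructed 40% coverage scene flips between theta 0.40 and 0.41", {
  lab1 <- matrix(0L, 8, 30)
  lab1[2:3, 3:7] <- 1L; lab1[6:7, 15:19] <- 2L   # two 10-px ROIs
  mask2 <- matrix(FALSE, 8, 30)
  mask2[2:3, 3:4] <- TRUE; mask2[6:7, 15:16] <- TRUE  # 4/10 of each
  expect_equal(roiOverlapRatio(lab1, mask2, 0.40), 1)
  expect_equal(roiOverlapRatio(lab1, mask2, 0.41), 0)
})

test_that("channel swap exchanges the metric directions", {
  sc1 <- generateScene(nPuncta = 6, width = 150, seed = 21)
  sc2 <- generateScene(nPuncta = 6, width = 150, seed = 22)
  l1 <- run_channel(channel(sc1$crop))$labels
  l2 <- run_channel(channel(sc2$crop))$labels
  m12 <- manders(l1 > 0, l2 > 0); m21 <- manders(l2 > 0, l1 > 0)
  expect_equal(unname(m12), unname(rev(m21)))
  cl <- colocalizeCrop(channel(sc1$crop), channel(sc2$crop), l1, l2, 0.25)
  cl_sw <- colocalizeCrop(channel(sc2$crop), channel(sc1$crop), l2, l1, 0.25)
  expect_equal(cl$r1, cl_sw$r2)
  expect_equal(cl$m1, cl_sw$m2)
  expect_equal(cl$pcc, cl_sw$pcc)
  expect_true(all(unlist(cl[c("m1", "m2", "r1", "r2")]) >= 0))
  expect_true(all(unlist(cl[c("m1", "m2", "r1", "r2")]) <= 1))
})
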