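test_that("scene generation is deterministic and honors degenerate specs", {
  a <- generateScene(nPuncta = 7, edgeConfounders = 2, seed = 12)
  b <- generateScene(nPuncta = 7, edgeConfounders = 2, seed = 12)
  expect_identical(channel(a$crop), channel(b$crop))
  expect_identical(a$truth, b$truth)

  z <- generateScene(nPuncta = 0, edgeConfounders = 0, readNoiseSd = 0,
                     background = 0.2, seed = 1)
  expect_true(all(channel(z$crop) == 0.2))
  expect_equal(max(z$truth), 0L)

  expect_error(generateScene(nPuncta = 50, width = 60, minSeparation = 30,
                             seed = 1),
               "cannot place")
})

test_that("ground truth is the half-maximum footprint of each punctum", {
  sc <- generateScene(nPuncta = 4, width = 200, minSeparation = 30,
                      readNoiseSd = 0, background = 0, seed = 8)
  img <- channel(sc$crop)
  for (k in seq_len(4)) {
    p <- sc$puncta[k, ]
    # noiseless contribution at the truth pixels is >= amplitude/2
    px <- which(sc$truth == k, arr.ind = TRUE)
    g <- p$amplitude * exp(-((px[, 1] - p$row)^2 + (px[, 2] - p$col)^2) /
                             (2 * p$sigma^2))
    expect_true(all(g >= p$amplitude / 2 - 1e-12))
    # the punctum center pixel carries its own label
    expect_equal(sc$truth[round(p$row), round(p$col)], k)
  }
})

test_that("edge confounders appear in the image but not in the truth", {
  base <- generateScene(nPuncta = 0, readNoiseSd = 0, edgeConfounders = 3,
                        seed = 44)
  expect_equal(max(base$truth), 0L)
  img <- channel(base$crop)
  expect_gt(max(img), 0.5)  # bright blobs present
  bright <- which(img > 0.5, arr.ind = TRUE)
  # confounders hug the y edges (within ~3 px bands plus blob spread)
  expect_true(all(bright[, 1] <= 7 | bright[, 1] >= nrow(img) - 6))
})

test_that("zero-parameter noise is the identity for non-Poisson kinds", {
  set.seed(3)
  img <- matrix(runif(400), 20, 20)
  expect_equal(addNoise(img, "gaussian", mean = 0, variance = 0), img)
  expect_equal(addNoise(img, "speckle", variance = 0), img)
  expect_equal(addNoise(img, "salt_pepper", density = 0), img)
})

test_that("salt-and-pepper replaces the configured pixel fraction with extremes", {
  img <- matrix(runif(10000, 0.3, 0.7), 100, 100)
  noisy <- addNoise(img, "salt_pepper", density = 0.05, seed = 99)
  changed <- sum(noisy != img)
  # binomial(10000, 0.05): 500 +/- ~4 sd
  expect_gt(changed, 500 - 4 * sqrt(10000 * 0.05 * 0.95))
  expect_lt(changed, 500 + 4 * sqrt(10000 * 0.05 * 0.95))
  ext <- noisy[noisy != img]
  expect_true(all(ext == min(img) | ext == max(img)))
})

test_that("noise moments match their models (Monte Carlo)", {
  # Poisson on a constant field: the counts-scale mean is preserved
  img <- matrix(0.5, 200, 500)  # rescales to all-zero range; use two values
  img[1, 1] <- 0; img[200, 500] <- 1
  noisy <- addNoise(img, "poisson", poissonScale = 1000, seed = 7)
  body <- noisy[img == 0.5]
  n <- length(body)
  # mean 0.5, sd sqrt(0.5/1000)
  expect_lt(abs(mean(body) - 0.5), 3 * sqrt(0.5 / 1000) / sqrt(n))
  # Gaussian: added noise has the requested mean and variance
  img2 <- matrix(0.5, 100, 100); img2[1, 1] <- 0; img2[100, 100] <- 1
  g <- addNoise(img2, "gaussian", mean = 0.1, variance = 0.01, seed = 8)
  diffs <- (g - img2)[img2 == 0.5]
  expect_lt(abs(mean(diffs) - 0.1), 0.005)
  expect_lt(abs(stats::sd(diffs) - 0.1), 0.005)
  # speckle: multiplicative uniform with the requested variance
  s <- addNoise(img2, "speckle", variance = 0.04, seed = 9)
  rel <- (s / img2 - 1)[img2 == 0.5]
  expect_lt(abs(stats::sd(rel) - 0.2), 0.01)
})

test_that("noise parameters outside the supported grids are rejected", {
  img <- matrix(runif(100), 10, 10)
  expect_error(addNoise(img, "gaussian", variance = 0.3), "0.2")
  expect_error(addNoise(img, "salt_pepper", density = 0.2), "density")
  expect_error(addNoise(img, "speckle", variance = -1), "variance")
})

test_that("noise is reproducible under a fixed seed without touching the RNG", {
  img <- matrix(runif(100), 10, 10)
  set.seed(1); before <- runif(1)
  set.seed(1)
  a <- addNoise(img, "gaussian", variance = 0.01, seed = 5)
  after <- runif(1)
  expect_identical(a, addNoise(img, "gaussian", variance = 0.01, seed = 5))
  expect_identical(before, after)  # caller's RNG stream undisturbed
})

test_that("the zero-noise point of a noise study scores 1 on all metrics", {
  crops <- lapply(1:3, function(i)
    generateScene(nPuncta = 6, width = 150, seed = 50 + i,
                  cropId = sprintf("s%d", i))$crop)
  grid <- data.frame(kind = "gaussian", mean = 0, variance = 0, density = NA)
  ns <- noiseStudy(crops, tuned_config(), grid = grid, theta = 0.3)
  expect_equal(ns$summary$pcc_normalized_mean, 1, tolerance = 1e-9)
  expect_equal(ns$summary$m1_mean, 1, tolerance = 1e-9)
  expect_equal(ns$summary$r1_mean, 1, tolerance = 1e-9)
})
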