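# Independent reference implementations used as oracles. Deliberately naive
# and slow: per-pixel loops, exhaustive searches.

# per-pixel sliding-window mean with edge replication
naive_window_mean <- function(x, w) {
  nr <- nrow(x); nc <- ncol(x); h <- (w - 1) / 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ri <- pmin(pmax((i - h):(i + h), 1), nr)
    ci <- pmin(pmax((j - h):(j + h), 1), nc)
    out[i, j] <- mean(x[ri, ci])
  }
  out
}

naive_bradley <- function(x, s, w) x > naive_window_mean(x, w) * 2 * (1 - s)

# exhaustive 256-bin Otsu: maximize between-class variance over all cuts
naive_otsu_threshold <- function(x01) {
  h <- tabulate(pmin(floor(x01 * 256) + 1, 256), nbins = 256)
  p <- h / sum(h)
  best <- -Inf; bestt <- 0
  for (k in 1:255) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mids <- (seq_len(256) - 0.5) / 256
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):256] * mids[(k + 1):256]) / w1
    v <- w0 * w1 * (mu0 - mu1)^2
    if (v > best) { best <- v; bestt <- k / 256 }
  }
  bestt
}

# scene with two equal-amplitude Gaussian puncta a fixed distance apart
two_gaussian_scene <- function(seed, sep = 8, sigma = 2,
                               height = 20, width = 48) {
  set.seed(seed)
  a <- runif(1, 0.6, 1)
  cy <- height / 2 + runif(1, -1, 1)
  cx <- runif(1, width / 2 - 9, width / 2 + 1)
  img <- matrix(0, height, width)
  for (i in seq_len(height)) for (j in seq_len(width))
    img[i, j] <- a * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2)) +
      a * exp(-((i - cy)^2 + (j - cx - sep)^2) / (2 * sigma^2))
  list(img = img, peaks = rbind(c(cy, cx), c(cy, cx + sep)), amplitude = a)
}

single_gaussian_scene <- function(seed, sigma = 2, height = 20, width = 40) {
  set.seed(seed)
  a <- runif(1, 0.6, 1)
  cy <- height / 2 + runif(1, -1, 1)
  cx <- runif(1, width / 2 - 2, width / 2 + 2)
  img <- matrix(0, height, width)
  for (i in seq_len(height)) for (j in seq_len(width))
    img[i, j] <- a * exp(-((i - cy)^2 + (j - cx)^2) / (2 * sigma^2))
  list(img = img, peak = c(cy, cx))
}

# random label map: rectangles dropped on a grid, later ones overwrite
random_label_map <- function(seed, nr = 20, nc = 60, n = 8) {
  set.seed(seed)
  lab <- matrix(0L, nr, nc)
  for (k in seq_len(n)) {
    h <- sample(1:4, 1); w <- sample(1:5, 1)
    r <- sample(1:(nr - h), 1); c <- sample(1:(nc - w), 1)
    lab[r:(r + h), c:(c + w)] <- k
  }
  # relabel contiguous by connected components of each id that survived
  out <- matrix(0L, nr, nc)
  nxt <- 0L
  for (k in seq_len(n)) {
    if (!any(lab == k)) next
    nxt <- nxt + 1L
    out[lab == k] <- nxt
  }
  out
}

# standard high-SNR detection settings used across end-to-end tests
tuned_config <- function() {
  AnalysisConfig(
    detection = DetectionParams(sensitivity = 0.1, neighborhood = 15),
    restriction = RestrictionParams(minArea = 5),
    pixelSize = 0.21
  )
}

run_channel <- function(ch, config = tuned_config(), channel = 1L) {
  det <- detectROIs(ch, config@detection[[channel]])
  tab <- measureROIs(det$labels, ch, config@pixelSize)
  if (nrow(tab) == 0)
    return(list(mask = det$mask, labels = det$labels, table = tab))
  r <- restrictROIs(det$labels, tab, config@restriction[[channel]])
  list(mask = det$mask, labels = r$labels, table = r$table)
}
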