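# Independent reference implementations used as oracles.

# Direct triple-sum evaluation of the self-similarity profile: a[l] by
# explicit summation with zero padding, gamma from the full-vector energy.
directSelfSimilarity <- function(x) {
  N <- length(x)
  lags <- -(N - 1):(N - 1)
  E <- sum(x^2)
  a <- vapply(lags, function(l) {
    s <- 0
    for (n in seq_len(N)) {
      k <- n - l
      if (k >= 1 && k <= N) s <- s + x[n] * x[k]
    }
    s
  }, numeric(1))
  list(lags = lags, r = a / E)
}

# z-normalize with population standard deviation
znorm <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))

# Distance from a 2D point to the ray from the origin along theta degrees
# (t >= 0).
distToRay <- function(p, thetaDeg) {
  d <- c(cos(thetaDeg * pi / 180), sin(thetaDeg * pi / 180))
  t <- max(0, sum(p * d))
  sqrt(sum((p - t * d)^2))
}

# Brute-force adjacent-triplet selection over an 8 x 3 point matrix.
bruteTriplet <- function(P) {
  n <- nrow(P)
  d <- sqrt(rowSums(P^2))
  best <- -Inf; bestIdx <- NULL
  for (i in seq_len(n)) {
    idx <- c(i, i %% n + 1, (i + 1) %% n + 1)
    s <- sum(d[idx])
    if (s > best + 1e-15) { best <- s; bestIdx <- idx }
  }
  list(indices = bestIdx, total = best)
}

# A quick dark-disk frame (no motion machinery) for cropping tests.
diskFrame <- function(size, centerRow, centerCol, radius) {
  img <- matrix(1, size, size)
  for (i in seq_len(size)) for (j in seq_len(size)) {
    if ((i - centerRow)^2 + (j - centerCol)^2 <= radius^2) img[i, j] <- 0
  }
  img
}

# Intensity-weighted dark centroid (duplicated here on purpose as a check).
darkCentroid <- function(img, threshold = 0.5) {
  w <- pmax(0, threshold - img)
  c(sum(row(img) * w), sum(col(img) * w)) / sum(w)
}

# Small fast motion parameters for integration tests.
fastParams <- function(v, phi, ppm = 125) {
  motionParameters(v = v, phi = phi, step = 2e-3, pixelsPerMeter = ppm)
}
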