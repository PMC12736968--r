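#' @include AllClasses.R
NULL

#' Normalized self-similarity profile of a scanline
#'
#' For a z-normalized scanline x of length N, computes
#' a[l] = sum_n x[n] x[n-l] with zero padding for out-of-range samples, and
#' normalizes by gamma = sqrt(E * E) where E = sum_n x[n]^2 is the
#' full-vector energy, giving r[l] = a[l] / gamma with r[0] = 1 and
#' |r[l]| <= 1. An all-zero scanline yields a profile of zeros flagged
#' invalid.
#'
#' Computed via FFT (linear autocorrelation by zero-padded circular
#' convolution); the direct triple-sum evaluation is the reference the test
#' suite checks against.
#'
#' @param x numeric scanline (typically a row of a normalized matrix).
#' @return a [SelfSimilarityProfile-class] with lags -(N-1)..(N-1).
#' @export
selfSimilarity <- function(x) {
  N <- length(x)
  if (N < 2) stop("scanline must have length >= 2")
  E <- sum(x^2)
  lags <- as.integer(-(N - 1):(N - 1))
  if (E < .Machine$double.xmin) {
    return(new("SelfSimilarityProfile", lags = lags,
               values = numeric(2 * N - 1), valid = FALSE))
  }
  L <- 2^ceiling(log2(2 * N))
  X <- stats::fft(c(x, rep(0, L - N)))
  a <- Re(stats::fft(X * Conj(X), inverse = TRUE)) / L
  vals <- c(rev(a[2:N]), a[1:N]) / E
  new("SelfSimilarityProfile", lags = lags, values = vals, valid = TRUE)
}

# local maxima of a numeric vector with plateau handling: runs of equal
# values count as one candidate at the run midpoint
.localMaxima <- function(r) {
  n <- length(r)
  if (n < 3) return(integer())
  rl <- rle(r)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  k <- length(rl$values)
  if (k < 3) return(integer())
  inner <- 2:(k - 1)
  isPeak <- rl$values[inner] > rl$values[inner - 1] &
            rl$values[inner] > rl$values[inner + 1]
  idx <- inner[isPeak]
  as.integer(floor((starts[idx] + ends[idx]) / 2))
}

# prominence by the lowest-contour-line definition: from the peak, walk in
# each direction until a higher value is met (or the signal ends); the
# prominence is peak height minus the higher of the two interval minima
.prominences <- function(r, peaks) {
  n <- length(r)
  vapply(peaks, function(p) {
    h <- r[p]
    i <- p; lmin <- h
    while (i > 1 && r[i - 1] <= h) { i <- i - 1; lmin <- min(lmin, r[i]) }
    i <- p; rmin <- h
    while (i < n && r[i + 1] <= h) { i <- i + 1; rmin <- min(rmin, r[i]) }
    h - max(lmin, rmin)
  }, numeric(1))
}

#' Prominence-filtered peaks of a self-similarity profile
#'
#' Local maxima of r over lags whose prominence (vertical distance between
#' the peak and its lowest contour line) reaches
#' \code{minProminence * r[0]}.
#'
#' @param profile a [SelfSimilarityProfile-class].
#' @param minProminence prominence threshold as a fraction of the zero-lag
#'   value.
#' @return data.frame with columns lag, value, prominence, sorted by lag.
#' @export
findProminentPeaks <- function(profile, minProminence = 0.05) {
  empty <- data.frame(lag = integer(), value = numeric(), prominence = numeric())
  if (!profile@valid) return(empty)
  r <- profile@values
  peaks <- .localMaxima(r)
  if (!length(peaks)) return(empty)
  prom <- .prominences(r, peaks)
  r0 <- r[profile@lags == 0L]
  keep <- prom >= minProminence * r0
  data.frame(lag = profile@lags[peaks[keep]], value = r[peaks[keep]],
             prominence = prom[keep])
}

#' Lag of the second most prominent self-similarity peak
#'
#' The zero-lag peak is the trivial self-match; the most prominent peak at a
#' nonzero lag locates the artifact replica. Ties in prominence are broken
#' toward the smaller |lag|, then toward the positive lag.
#'
#' @param profile a [SelfSimilarityProfile-class].
#' @param minProminence prominence threshold as a fraction of r[0].
#' @return integer lag, or NA when no nonzero-lag peak qualifies.
#' @export
secondPeakLag <- function(profile, minProminence = 0.05) {
  pk <- findProminentPeaks(profile, minProminence)
  pk <- pk[pk$lag != 0L, , drop = FALSE]
  if (!nrow(pk)) return(NA_integer_)
  ord <- order(-pk$prominence, abs(pk$lag), -sign(pk$lag))
  as.integer(pk$lag[ord[1]])
}

#' Per-scanline artifact peak lags of a normalized matrix
#'
#' Applies [secondPeakLag()] to every scanline; invalid (all-zero) scanlines
#' yield missing entries. The complement set is the negation of the detected
#' lags (symmetry-based lag complementation).
#'
#' @param norm a [NormalizedMatrix-class].
#' @param minProminence prominence threshold as a fraction of r[0].
#' @return a [PeakLocations-class].
#' @export
scanMatrix <- function(norm, minProminence = 0.05) {
  K <- nrow(norm@values)
  lags <- rep(NA_real_, K)
  proms <- rep(NA_real_, K)
  for (k in seq_len(K)) {
    if (!norm@validRowMask[k]) next
    prof <- selfSimilarity(norm@values[k, ])
    pk <- findProminentPeaks(prof, minProminence)
    pk <- pk[pk$lag != 0L, , drop = FALSE]
    if (!nrow(pk)) next
    ord <- order(-pk$prominence, abs(pk$lag), -sign(pk$lag))
    lags[k] <- pk$lag[ord[1]]
    proms[k] <- pk$prominence[ord[1]]
  }
  new("PeakLocations", lags = lags, prominences = proms)
}

#' Detected and complement lag sets
#'
#' @param peaks a [PeakLocations-class].
#' @return list with elements \code{pLoc} (detected lags, missing dropped)
#'   and \code{pBarLoc} (their negation).
#' @export
peakSets <- function(peaks) {
  p <- peaks@lags[!is.na(peaks@lags)]
  list(pLoc = p, pBarLoc = -p)
}
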