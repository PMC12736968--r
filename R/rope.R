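#' @include AllClasses.R
NULL

#' Exponential moving average of a scanline
#'
#' EMA[1] = x[1]; EMA[j] = alpha * x[j] + (1 - alpha) * EMA[j-1].
#'
#' @param x numeric vector of length >= 2.
#' @param alpha smoothing coefficient in (0, 1]; alpha = 1 returns x.
#' @return numeric vector of the same length.
#' @export
emaSmooth <- function(x, alpha = 0.3) {
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (length(x) < 2) stop("scanline must have length >= 2")
  as.numeric(stats::filter(c(x[1], alpha * x[-1]), 1 - alpha,
                           method = "recursive"))
}

#' First differences of a smoothed scanline
#'
#' s[j] = EMA[j+1] - EMA[j]; the slope at index j refers to the left
#' endpoint of the difference.
#'
#' @param ema numeric vector of length >= 2.
#' @return numeric vector of length length(ema) - 1.
#' @export
slopeSequence <- function(ema) {
  if (length(ema) < 2) stop("need at least two samples")
  diff(ema)
}

#' Reference origin per scanline
#'
#' For each scanline, smooths with an EMA, takes first differences and
#' locates the dominant transition g = argmax |s| (ties toward the smallest
#' index, reported at the left endpoint). A global threshold
#' T = tauRope * max_i(vhat_i), where vhat_i is scanline i's maximum
#' absolute slope, discards weak transitions: an origin is retained iff its
#' slope magnitude reaches T and is strictly positive (so a flat matrix
#' retains nothing, while tauRope = 1 retains exactly the scanlines
#' achieving the global maximum).
#'
#' @param norm a [NormalizedMatrix-class].
#' @param alpha EMA smoothing coefficient.
#' @param tauRope threshold fraction in (0, 1].
#' @return a [ReferenceOrigins-class].
#' @export
referenceOrigins <- function(norm, alpha = 0.3, tauRope = 0.3) {
  if (tauRope <= 0 || tauRope > 1) stop("tauRope must lie in (0, 1]")
  K <- nrow(norm@values)
  origins <- rep(NA_real_, K)
  vhat <- numeric(K)
  for (k in seq_len(K)) {
    if (!norm@validRowMask[k]) next
    s <- slopeSequence(emaSmooth(norm@values[k, ], alpha))
    g <- which.max(abs(s))
    origins[k] <- g
    vhat[k] <- abs(s[g])
  }
  thr <- tauRope * max(vhat)
  keep <- vhat >= thr & vhat > 0
  origins[!keep] <- NA_real_
  new("ReferenceOrigins", origins = origins, maxSlopes = vhat, threshold = thr)
}
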