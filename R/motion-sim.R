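#' @include AllClasses.R config.R
NULL

#' Number of trajectory samples
#' @param params a [MotionParameters-class].
#' @return floor(exposure / step).
#' @export
nSamples <- function(params) as.integer(floor(params@exposure / params@step))

#' Evaluate the motion trajectory
#'
#' Position of the object center at time t, in pixels relative to the
#' trajectory origin: a circular oscillation of radius A plus a linear
#' drift of pixel velocity v * pixelsPerMeter along orientation phi,
#' \deqn{r(t) = (A\cos\omega t - v_{px} t \cos\varphi,\;
#'               A\sin\omega t - v_{px} t \sin\varphi).}
#'
#' @param params a [MotionParameters-class].
#' @param t time in seconds, 0 <= t <= exposure (vectorized).
#' @return a matrix with columns x, y (one row per time point).
#' @examples
#' trajectory(motionParameters(A = 1, omega = pi / 2, v = 0), 1)  # (0, 1)
#' @export
trajectory <- function(params, t) {
  if (any(t < 0 | t > params@exposure))
    stop("t must lie within [0, exposure]")
  vpx <- params@v * params@pixelsPerMeter
  phi <- params@phi * pi / 180
  cbind(x = params@A * cos(params@omega * t) - vpx * t * cos(phi),
        y = params@A * sin(params@omega * t) - vpx * t * sin(phi))
}

# analytic trajectory derivative (px/s)
.trajectorySpeed <- function(params, t) {
  vpx <- params@v * params@pixelsPerMeter
  phi <- params@phi * pi / 180
  dx <- -params@A * params@omega * sin(params@omega * t) - vpx * cos(phi)
  dy <- params@A * params@omega * cos(params@omega * t) - vpx * sin(phi)
  sqrt(dx^2 + dy^2)
}

#' Arc length of the motion trajectory over the exposure
#'
#' Integrates the instantaneous trajectory speed |r'(t)| over [0, exposure]
#' by adaptive quadrature. This is the total path length of the combined
#' oscillatory and drift motion, in pixels, which governs the elongation of
#' the blur. Closed-form limits: A * omega * exposure when v = 0 (pure
#' oscillation) and v * pixelsPerMeter * exposure when A = 0 (pure drift).
#'
#' @param params a [MotionParameters-class].
#' @return path length in pixels.
#' @export
arcLength <- function(params) {
  stats::integrate(function(t) .trajectorySpeed(params, t),
                   lower = 0, upper = params@exposure,
                   subdivisions = 2000L, rel.tol = 1e-9)$value
}

# discrete PSF kernel evaluated at offsets (dy, dx) from a sub-pixel center
.gaussKernel1d <- function(sigma, radius) {
  k <- exp(-((-radius:radius)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable gaussian smoothing with edge replication
.gaussSmooth <- function(img, sigma, radius = ceiling(3 * sigma)) {
  if (sigma <= 0) return(img)
  k <- .gaussKernel1d(sigma, radius)
  convAlong <- function(m) {
    n <- ncol(m)
    padded <- cbind(matrix(m[, 1], nrow(m), radius), m,
                    matrix(m[, n], nrow(m), radius))
    out <- matrix(0, nrow(m), n)
    for (i in seq_along(k)) out <- out + k[i] * padded[, i:(i + n - 1)]
    out
  }
  t(convAlong(t(convAlong(img))))
}

# sampled trajectory mapped to frame pixel coordinates; the bounding-box
# center of the sampled path is placed at the frame center pixel
.sampledPath <- function(params, shape) {
  n <- nSamples(params)
  if (n < 1) stop("no trajectory samples: exposure/step < 1")
  tn <- (seq_len(n) - 1) * params@step
  rt <- trajectory(params, tn)
  # geometric frame center (fractional for even sizes, keeping the
  # rendering symmetric under 90-degree rotations)
  cr <- (shape[1] + 1) / 2
  cc <- (shape[2] + 1) / 2
  x <- rt[, "x"] - mean(range(rt[, "x"]))
  y <- rt[, "y"] - mean(range(rt[, "y"]))
  # y up on screen: larger y means smaller row index
  list(row = cr - y, col = cc + x, n = n)
}

#' Render a point trail
#'
#' Accumulates the PSF kernel centered at each sampled trajectory position
#' into an initially black frame, then rescales to [0, 1]. Delta kernels are
#' placed at the nearest integer pixel; gaussian kernels are evaluated at
#' the true sub-pixel offsets over their truncated support. Samples whose
#' support extends beyond the frame contribute only their in-frame part
#' (with a warning).
#'
#' @param params a [MotionParameters-class].
#' @param psf a [PSFSpec-class].
#' @param shape frame dimensions c(rows, cols).
#' @return a [SyntheticFrame-class]; \code{meta$totalMass} holds the
#'   accumulated (pre-rescale) kernel mass.
#' @export
renderPointTrail <- function(params, psf = psfSpec("delta"),
                             shape = c(256, 256)) {
  path <- .sampledPath(params, shape)
  acc <- matrix(0, shape[1], shape[2])
  clipped <- FALSE
  if (psf@kind == "delta") {
    ri <- round(path$row); ci <- round(path$col)
    ok <- ri >= 1 & ri <= shape[1] & ci >= 1 & ci <= shape[2]
    clipped <- any(!ok)
    for (idx in which(ok)) acc[ri[idx], ci[idx]] <- acc[ri[idx], ci[idx]] + 1
  } else {
    rad <- psf@supportRadius
    off <- expand.grid(di = -rad:rad, dj = -rad:rad)
    for (k in seq_len(path$n)) {
      r0 <- path$row[k]; c0 <- path$col[k]
      ri <- round(r0) + off$di; ci <- round(c0) + off$dj
      w <- exp(-((ri - r0)^2 + (ci - c0)^2) / (2 * psf@sigma^2))
      w <- w / sum(w)
      ok <- ri >= 1 & ri <= shape[1] & ci >= 1 & ci <= shape[2]
      if (any(!ok)) clipped <- TRUE
      idx <- cbind(ri[ok], ci[ok])
      acc[idx] <- acc[idx] + w[ok]
    }
  }
  if (clipped)
    warning("trajectory support extends beyond the frame; contributions clipped")
  total <- sum(acc)
  if (total == 0) stop("trajectory entirely outside the frame")
  out <- acc / max(acc)
  new("SyntheticFrame", intensities = out,
      truthPhi = params@phi, truthV = params@v,
      meta = list(params = params, psf = psf, shape = shape,
                  renderer = "point", totalMass = total))
}

#' Render an object trail (dark disk on white background)
#'
#' Sweeps a dark disk along the trajectory and accumulates per-pixel
#' coverage time (the exposure integral of the moving-object indicator,
#' i.e. the object indicator convolved with the trajectory measure). The
#' accumulated coverage is normalized by its maximum and inverted to a
#' dark-on-white frame, then smoothed by the PSF. Because coverage is a
#' time integral, positions where the trajectory dwells (the once-per-cycle
#' speed minima of the oscillation) come out darker, producing the replica
#' copies of the object that constitute the movement artifact.
#'
#' @param params a [MotionParameters-class].
#' @param psf a [PSFSpec-class]; gaussian smooths the rendered frame, delta
#'   leaves it as rendered.
#' @param objectRadius radius of the dark disk in pixels (> 0).
#' @param shape frame dimensions c(rows, cols).
#' @param noiseSd standard deviation of optional additive zero-mean gaussian
#'   pixel noise (0 disables; result clipped back to [0, 1]).
#' @param noiseSeed integer seed used when noiseSd > 0.
#' @return a [SyntheticFrame-class].
#' @examples
#' fr <- renderObjectTrail(motionParameters(v = 0.24, phi = 30))
#' @export
renderObjectTrail <- function(params, psf = psfSpec("gaussian", sigma = 1),
                              objectRadius = 2, shape = c(256, 256),
                              noiseSd = 0, noiseSeed = 1L) {
  if (objectRadius <= 0) stop("objectRadius must be > 0")
  if (2 * objectRadius + 1 > min(shape)) stop("object disk larger than the frame")
  path <- .sampledPath(params, shape)
  r <- ceiling(objectRadius)
  off <- expand.grid(di = -r:r, dj = -r:r)
  off <- off[off$di^2 + off$dj^2 <= objectRadius^2, , drop = FALSE]
  cov <- matrix(0, shape[1], shape[2])
  rows <- round(path$row); cols <- round(path$col)
  clipped <- FALSE
  for (k in seq_len(path$n)) {
    ri <- rows[k] + off$di; ci <- cols[k] + off$dj
    ok <- ri >= 1 & ri <= shape[1] & ci >= 1 & ci <= shape[2]
    if (any(!ok)) clipped <- TRUE
    idx <- cbind(ri[ok], ci[ok])
    cov[idx] <- cov[idx] + 1
  }
  if (clipped)
    warning("trajectory support extends beyond the frame; contributions clipped")
  if (max(cov) == 0) stop("trajectory entirely outside the frame")
  img <- 1 - cov / max(cov)
  if (psf@kind == "gaussian")
    img <- .gaussSmooth(img, psf@sigma, psf@supportRadius)
  if (noiseSd > 0) {
    set.seed(as.integer(noiseSeed))
    img <- img + matrix(stats::rnorm(length(img), sd = noiseSd),
                        nrow(img), ncol(img))
  }
  img <- matrix(pmin(1, pmax(0, img)), nrow(img), ncol(img))
  new("SyntheticFrame", intensities = img,
      truthPhi = params@phi, truthV = params@v,
      meta = list(params = params, psf = psf, shape = shape,
                  objectRadius = objectRadius, renderer = "object",
                  noiseSd = noiseSd,
                  noiseSeed = if (noiseSd > 0) as.integer(noiseSeed) else NA_integer_))
}

#' Generate a grid of ground-truthed synthetic frames
#'
#' One object-trail frame per (phi, v) combination, deterministic for fixed
#' inputs (noise, when enabled, uses a per-frame seed derived from the grid
#' position).
#'
#' @param phis orientations in degrees.
#' @param vs velocities in m/s.
#' @param common a [MotionParameters-class] supplying all non-(phi, v)
#'   parameters.
#' @param psf a [PSFSpec-class].
#' @param objectRadius dark disk radius in pixels.
#' @param shape frame dimensions.
#' @param noiseSd additive noise level (0 disables).
#' @param seed base seed for the optional noise.
#' @return a list of [SyntheticFrame-class] objects, phi varying fastest.
#' @examples
#' grid <- makeFixtureGrid(c(0, 90), 0.24, shape = c(96, 96))
#' length(grid)
#' @export
makeFixtureGrid <- function(phis, vs, common = motionParameters(),
                            psf = psfSpec("gaussian", sigma = 1),
                            objectRadius = 2, shape = c(256, 256),
                            noiseSd = 0, seed = 1L) {
  if (!length(phis) || !length(vs)) stop("phis and vs must be nonempty")
  frames <- vector("list", length(phis) * length(vs))
  k <- 0L
  for (v in vs) for (phi in phis) {
    k <- k + 1L
    p <- motionParameters(A = common@A, omega = common@omega, v = v,
                          phi = phi, exposure = common@exposure,
                          step = common@step,
                          pixelsPerMeter = common@pixelsPerMeter)
    frames[[k]] <- renderObjectTrail(p, psf, objectRadius, shape,
                                     noiseSd = noiseSd,
                                     noiseSeed = seed + k)
  }
  frames
}
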