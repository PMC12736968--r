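#' @include AllClasses.R estimate.R motion-sim.R
NULL

#' Angular error on the circle
#'
#' AE = min(|theta - phi|, 360 - |theta - phi|), in [0, 180]; symmetric in
#' its arguments.
#'
#' @param thetaEst estimated direction in degrees.
#' @param phiGt ground-truth orientation in degrees.
#' @return angular error in degrees (vectorized).
#' @export
angularError <- function(thetaEst, phiGt) {
  d <- abs(thetaEst - phiGt) %% 360
  pmin(d, 360 - d)
}

#' Orientation-class error
#'
#' min(AE, 180 - AE), in [0, 90]: a movement artifact is bidirectional, so
#' an estimate 180 degrees from the truth still indicates the correct
#' orientation class.
#'
#' @param thetaEst estimated direction in degrees.
#' @param phiGt ground-truth orientation in degrees.
#' @return orientation-class error in degrees (vectorized).
#' @export
orientationError <- function(thetaEst, phiGt) {
  ae <- angularError(thetaEst, phiGt)
  pmin(ae, 180 - ae)
}

#' Run an orientation x velocity estimation sweep
#'
#' Simulates one object-trail frame per (phi, v) combination and estimates
#' its artifact direction and magnitude. Individual estimation failures
#' (no object, no artifact signal) are recorded as missing estimates, not
#' aborts. Deterministic for fixed configuration.
#'
#' @param phis orientations in degrees.
#' @param vs velocities in m/s.
#' @param common a [MotionParameters-class] supplying the non-(phi, v)
#'   trajectory parameters.
#' @param psf a [PSFSpec-class] for the renderer.
#' @param objectRadius dark disk radius in pixels.
#' @param shape simulated frame dimensions.
#' @param config a [PipelineConfig-class] for the estimator.
#' @param csv optional path; when given, the records are also written as
#'   CSV with exactly these columns.
#' @return data.frame with columns phi_gt, v, theta_est, q_est, AE, AE180.
#' @export
runSweep <- function(phis, vs, common = motionParameters(),
                     psf = psfSpec("gaussian", sigma = 1),
                     objectRadius = 2, shape = c(256, 256),
                     config = pipelineConfig(), csv = NULL) {
  if (!length(phis) || !length(vs)) stop("phis and vs must be nonempty")
  rows <- vector("list", length(phis) * length(vs))
  k <- 0L
  for (v in vs) for (phi in phis) {
    k <- k + 1L
    p <- motionParameters(A = common@A, omega = common@omega, v = v,
                          phi = phi, exposure = common@exposure,
                          step = common@step,
                          pixelsPerMeter = common@pixelsPerMeter)
    fr <- renderObjectTrail(p, psf, objectRadius, shape)
    est <- tryCatch(estimateDirection(fr, config), error = function(e) NULL)
    rows[[k]] <- data.frame(
      phi_gt = phi, v = v,
      theta_est = if (is.null(est)) NA_real_ else est@theta,
      q_est = if (is.null(est)) NA_real_ else est@q,
      AE = if (is.null(est)) NA_real_ else angularError(est@theta, phi),
      AE180 = if (is.null(est)) NA_real_ else orientationError(est@theta, phi))
  }
  records <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(format(records, digits = 15), csv,
                                      row.names = FALSE, quote = FALSE)
  records
}

#' Combined performance map over a sweep grid
#'
#' Per (phi, v) cell score in [0, 1]: the mean of the min-max-normalized
#' orientation-class error and the min-max-normalized magnitude deficit
#' (1 - scaled q). 0 indicates optimal performance and 1 the boundary
#' limitation. Missing estimates take the worst value of each term. A term
#' whose range over the grid is degenerate (constant) normalizes to 0; the
#' normalization bounds are returned so the scores are reproducible.
#'
#' @param records a sweep data.frame from [runSweep()].
#' @return list(map = data.frame(phi_gt, v, score), bounds = list(ae180 =
#'   c(min, max), q = c(min, max))).
#' @export
performanceMap <- function(records) {
  minmax <- function(x) {
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
      list(scaled = rep(0, length(x)), rng = rng)
    } else {
      list(scaled = (x - rng[1]) / (rng[2] - rng[1]), rng = rng)
    }
  }
  ae <- minmax(records$AE180)
  qm <- minmax(records$q_est)
  aeTerm <- ae$scaled
  aeTerm[is.na(aeTerm)] <- if (diff(ae$rng) > 0) 1 else 0
  qTerm <- if (diff(range(records$q_est, na.rm = TRUE)) > 0) 1 - qm$scaled
           else rep(0, nrow(records))
  qTerm[is.na(qTerm)] <- if (diff(qm$rng) > 0) 1 else 0
  data.frame(phi_gt = records$phi_gt, v = records$v,
             score = (aeTerm + qTerm) / 2) -> map
  list(map = map, bounds = list(ae180 = ae$rng, q = qm$rng))
}

#' Quadratic trend of performance scores over velocity
#'
#' Reporting utility: least-squares quadratic polynomial of the mean
#' per-velocity score as a function of v.
#'
#' @param perf output of [performanceMap()].
#' @return the fitted \code{lm} object (score ~ poly(v, 2)).
#' @export
fitPerformanceTrend <- function(perf) {
  agg <- stats::aggregate(score ~ v, data = perf$map, FUN = mean)
  stats::lm(score ~ stats::poly(v, 2), data = agg)
}
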