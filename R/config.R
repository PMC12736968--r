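#' @include AllClasses.R
NULL

#' Construct motion parameters
#'
#' Defaults describe the simulator's reference condition: a 2 px circular
#' oscillation at 6*pi rad/s (three cycles over the 1 s exposure) combined
#' with a 0.2 m/s drift, calibrated at 125 px/m so that the default drift
#' covers 25 px. The oscillation-to-drift ratio makes the object dwell once
#' per cycle, leaving replica copies of the object spaced by the drift per
#' cycle along the drift orientation; this is the replica structure the
#' estimation pipeline detects.
#'
#' @param A oscillation amplitude in pixels.
#' @param omega oscillation angular frequency in rad/s.
#' @param v drift velocity in m/s.
#' @param phi drift orientation in degrees; normalized into [0, 360).
#' @param exposure exposure time T in seconds.
#' @param step integration step s in seconds.
#' @param pixelsPerMeter pixel calibration.
#' @return a [MotionParameters-class] object.
#' @examples
#' p <- motionParameters(v = 0.24, phi = 30)
#' trajectory(p, 0.5)
#' @export
motionParameters <- function(A = 2, omega = 6 * pi, v = 0.2, phi = 0,
                             exposure = 1, step = 1e-3, pixelsPerMeter = 125) {
  new("MotionParameters", A = A, omega = omega, v = v, phi = phi %% 360,
      exposure = exposure, step = step, pixelsPerMeter = pixelsPerMeter)
}

#' Construct a PSF specification
#'
#' @param kind "gaussian" or "delta".
#' @param sigma gaussian spread in pixels.
#' @param supportRadius truncation radius in pixels; defaults to
#'   ceiling(3 * sigma) for gaussian and 0 for delta.
#' @return a [PSFSpec-class] object.
#' @export
psfSpec <- function(kind = c("gaussian", "delta"), sigma = 1,
                    supportRadius = NULL) {
  kind <- match.arg(kind)
  if (is.null(supportRadius))
    supportRadius <- if (kind == "gaussian") ceiling(3 * sigma) else 0
  new("PSFSpec", kind = kind, sigma = sigma, supportRadius = supportRadius)
}

#' Construct a pipeline configuration
#'
#' @param alpha EMA smoothing coefficient in (0, 1]. Smaller values smooth
#'   more aggressively before the slope search of the origin estimator.
#' @param tauRope origin-retention threshold as a fraction of the maximum
#'   per-scanline slope across the matrix, in (0, 1].
#' @param tauMaq plausibility threshold in pixels; displacements larger in
#'   magnitude are suppressed. Defaults to half the crop side: artifacts
#'   longer than half the analysis window are outside the model's regime.
#' @param beta boost factor applied to the directional standard deviations
#'   before the reliability swap.
#' @param minProminence minimum peak prominence, as a fraction of the
#'   zero-lag self-similarity value, for a lag to count as an artifact peak.
#' @param cropSide side of the square analysis window in pixels.
#' @param epsilonParallel determinant magnitude below which a ray and a
#'   polygon edge are treated as parallel (midpoint fallback).
#' @param lagMapping strategy mapping a detected lag l to candidate artifact
#'   positions; "origin-centered" uses g + l and g - l around the reference
#'   origin g, so |q| equals the detected lag magnitude.
#' @param backgroundThreshold intensity below which a pixel is treated as
#'   part of the dark object when centering.
#' @param diagFraction minimum diagonal length, as a fraction of the crop
#'   side, for a diagonal scanline to be retained.
#' @return a [PipelineConfig-class] object.
#' @examples
#' cfg <- pipelineConfig(beta = 2)
#' @export
pipelineConfig <- function(alpha = 0.3, tauRope = 0.3, tauMaq = cropSide / 2,
                           beta = 1, minProminence = 0.05, cropSide = 224,
                           epsilonParallel = 1e-10,
                           lagMapping = "origin-centered",
                           backgroundThreshold = 0.5, diagFraction = 0.5) {
  new("PipelineConfig", alpha = alpha, tauRope = tauRope, tauMaq = tauMaq,
      beta = beta, minProminence = minProminence, cropSide = cropSide,
      epsilonParallel = epsilonParallel, lagMapping = lagMapping,
      backgroundThreshold = backgroundThreshold, diagFraction = diagFraction,
      convention = "xy: x right, y up, angles counterclockwise from +x")
}

#' Load a pipeline configuration from a key=value file
#'
#' Reads a flat text file of \code{key=value} lines (blank lines and lines
#' starting with \code{#} ignored), applies \code{overrides} on top, and
#' validates every parameter range. Unknown keys raise an error naming the
#' key; out-of-range values raise an error naming the parameter and its
#' legal range.
#'
#' @param path path to the configuration file, or NULL for defaults only.
#' @param overrides named list of parameter overrides (these win over the
#'   file).
#' @return a [PipelineConfig-class] object.
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L)
        stop("malformed config line: '", ln, "'")
      vals[[trimws(kv[1])]] <- trimws(kv[2])
    }
  }
  for (k in names(overrides)) vals[[k]] <- overrides[[k]]
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  numeric.keys <- setdiff(known, "lagMapping")
  for (k in names(vals)) {
    if (k %in% numeric.keys && is.character(vals[[k]])) {
      x <- suppressWarnings(as.numeric(vals[[k]]))
      if (is.na(x)) stop("configuration key '", k, "' is not numeric: ", vals[[k]])
      vals[[k]] <- x
    }
  }
  do.call(pipelineConfig, vals)
}

#' Configuration digest for logging
#'
#' A single reproducibility line: every parameter of the configuration in a
#' stable order, plus the coordinate convention tag.
#'
#' @param config a [PipelineConfig-class].
#' @return a character scalar.
#' @export
configDigest <- function(config) {
  paste0(
    sprintf("alpha=%g tauRope=%g tauMaq=%g beta=%g minProminence=%g ",
            config@alpha, config@tauRope, config@tauMaq, config@beta,
            config@minProminence),
    sprintf("cropSide=%g epsilonParallel=%g lagMapping=%s [%s]",
            config@cropSide, config@epsilonParallel, config@lagMapping,
            config@convention)
  )
}
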