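#' @include AllClasses.R
NULL

#' Frame intensity matrix
#' @param object a SyntheticFrame.
#' @return the M x N intensity matrix in [0, 1].
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
setMethod("intensities", "SyntheticFrame", function(object) object@intensities)

#' Ground-truth orientation of a synthetic frame
#' @param object a SyntheticFrame.
#' @return orientation phi in degrees.
#' @export
setGeneric("truthPhi", function(object) standardGeneric("truthPhi"))

#' @rdname truthPhi
setMethod("truthPhi", "SyntheticFrame", function(object) object@truthPhi)

#' Ground-truth velocity of a synthetic frame
#' @param object a SyntheticFrame.
#' @return velocity v in m/s.
#' @export
setGeneric("truthV", function(object) standardGeneric("truthV"))

#' @rdname truthV
setMethod("truthV", "SyntheticFrame", function(object) object@truthV)

#' Estimated artifact direction
#' @param object a DirectionEstimate.
#' @return direction theta in degrees, in [0, 360).
#' @export
setGeneric("theta", function(object) standardGeneric("theta"))

#' @rdname theta
setMethod("theta", "DirectionEstimate", function(object) object@theta)

#' Weighted artifact magnitude
#' @param object a DirectionEstimate.
#' @return magnitude q in pixels.
#' @export
setGeneric("weightedMagnitude", function(object) standardGeneric("weightedMagnitude"))

#' @rdname weightedMagnitude
setMethod("weightedMagnitude", "DirectionEstimate", function(object) object@q)

#' @export
setMethod("show", "MotionParameters", function(object) {
  cat("MotionParameters\n")
  cat(sprintf("  oscillation: A = %g px, omega = %g rad/s\n", object@A, object@omega))
  cat(sprintf("  drift:       v = %g m/s at phi = %g deg (%g px over exposure)\n",
              object@v, object@phi,
              object@v * object@pixelsPerMeter * object@exposure))
  cat(sprintf("  exposure:    T = %g s, step = %g s (%d samples)\n",
              object@exposure, object@step, nSamples(object)))
  cat(sprintf("  calibration: %g px/m\n", object@pixelsPerMeter))
})

setMethod("show", "SyntheticFrame", function(object) {
  d <- dim(object@intensities)
  cat(sprintf("SyntheticFrame %d x %d  (phi = %g deg, v = %g m/s)\n",
              d[1], d[2], object@truthPhi, object@truthV))
  cat(sprintf("  intensity range [%.3f, %.3f]\n",
              min(object@intensities), max(object@intensities)))
})

setMethod("show", "DirectionalStats", function(object) {
  cat("DirectionalStats (beta =", object@beta, ")\n")
  print(data.frame(direction = object@directions, qbar = object@qbar,
                   sigma = object@sigma, reliability = object@reliability,
                   nValid = object@nValid))
})

setMethod("show", "PointOctagon", function(object) {
  cat("PointOctagon, center (", object@center[1], ",", object@center[2], ")\n")
  m <- object@points
  dimnames(m) <- list(paste0("p", 1:8), c("x", "y", "z"))
  print(round(m, 4))
})

setMethod("show", "DirectionEstimate", function(object) {
  cat("DirectionEstimate\n")
  cat(sprintf("  theta     = %.2f deg (complement %.2f deg)\n",
              object@theta, object@thetaComplement))
  cat(sprintf("  magnitude = %.2f px\n", object@q))
  tri <- object@diagnostics$triplet
  if (!is.null(tri))
    cat(sprintf("  triplet   = (%s), segment %d\n",
                paste(tri@indices, collapse = ", "),
                object@diagnostics$segmentIndex))
})
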