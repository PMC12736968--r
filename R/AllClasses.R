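#' @import methods
NULL

#' Motion trajectory and exposure parameters
#'
#' Describes the continuous-time trajectory of the imaged object during one
#' exposure: a circular oscillation of amplitude \code{A} (pixels) at angular
#' frequency \code{omega} (rad/s), superimposed on a linear drift at velocity
#' \code{v} (m/s) along orientation \code{phi} (degrees). The exposure lasts
#' \code{exposure} seconds and is discretised at \code{step} seconds;
#' \code{pixelsPerMeter} calibrates the drift into pixel units.
#'
#' Coordinate convention: x increases to the right, y increases upward on
#' screen, and angles are measured counterclockwise from the +x axis, so
#' phi = 90 points up the frame. The same convention is shared by the
#' estimator ([estimateDirection()]) and all reported angles.
#'
#' @slot A oscillation amplitude in pixels (>= 0).
#' @slot omega angular frequency in rad/s (>= 0).
#' @slot v drift velocity in m/s (>= 0).
#' @slot phi drift orientation in degrees, normalized to [0, 360).
#' @slot exposure exposure time T in seconds (> 0).
#' @slot step integration time step s in seconds (0 < step <= exposure).
#' @slot pixelsPerMeter pixel calibration (> 0).
#' @seealso [motionParameters()], [trajectory()], [arcLength()]
#' @exportClass MotionParameters
setClass("MotionParameters",
  representation(
    A = "numeric", omega = "numeric", v = "numeric", phi = "numeric",
    exposure = "numeric", step = "numeric", pixelsPerMeter = "numeric"
  )
)

setValidity("MotionParameters", function(object) {
  msg <- character()
  num1 <- function(x) length(x) == 1L && is.finite(x)
  if (!num1(object@A) || object@A < 0) msg <- c(msg, "A must be a single finite value >= 0")
  if (!num1(object@omega) || object@omega < 0) msg <- c(msg, "omega must be a single finite value >= 0")
  if (!num1(object@v) || object@v < 0) msg <- c(msg, "v must be a single finite value >= 0")
  if (!num1(object@phi) || object@phi < 0 || object@phi >= 360)
    msg <- c(msg, "phi must lie in [0, 360)")
  if (!num1(object@exposure) || object@exposure <= 0) msg <- c(msg, "exposure must be > 0")
  if (!num1(object@step) || object@step <= 0 || object@step > object@exposure)
    msg <- c(msg, "step must satisfy 0 < step <= exposure")
  if (!num1(object@pixelsPerMeter) || object@pixelsPerMeter <= 0)
    msg <- c(msg, "pixelsPerMeter must be > 0")
  if (length(msg) == 0L && floor(object@exposure / object@step) < 1)
    msg <- c(msg, "exposure/step must allow at least one sample")
  if (length(msg)) msg else TRUE
})

#' Point-spread-function specification
#'
#' Either an isotropic gaussian of spread \code{sigma} pixels, truncated at
#' \code{supportRadius} pixels and renormalized to unit mass over its discrete
#' support, or an ideal single-pixel impulse (\code{"delta"}).
#'
#' @slot kind "gaussian" or "delta".
#' @slot sigma gaussian spread in pixels (> 0; ignored for delta).
#' @slot supportRadius truncation radius in pixels.
#' @exportClass PSFSpec
setClass("PSFSpec",
  representation(kind = "character", sigma = "numeric", supportRadius = "numeric")
)

setValidity("PSFSpec", function(object) {
  msg <- character()
  if (!object@kind %in% c("gaussian", "delta"))
    msg <- c(msg, "kind must be 'gaussian' or 'delta'")
  if (object@kind == "gaussian" && (!is.finite(object@sigma) || object@sigma <= 0))
    msg <- c(msg, "sigma must be > 0 for a gaussian PSF")
  if (!is.finite(object@supportRadius) || object@supportRadius < 0)
    msg <- c(msg, "supportRadius must be >= 0")
  if (length(msg)) msg else TRUE
})

#' A simulated motion-blurred frame with ground truth
#'
#' @slot intensities M x N numeric matrix of intensities in [0, 1]
#'   (0 = black, 1 = white).
#' @slot truthPhi ground-truth drift orientation in degrees.
#' @slot truthV ground-truth drift velocity in m/s.
#' @slot meta list of generator parameters (trajectory, PSF, rendering).
#' @seealso [renderPointTrail()], [renderObjectTrail()], [makeFixtureGrid()]
#' @exportClass SyntheticFrame
setClass("SyntheticFrame",
  representation(
    intensities = "matrix", truthPhi = "numeric", truthV = "numeric",
    meta = "list"
  )
)

setValidity("SyntheticFrame", function(object) {
  v <- object@intensities
  if (!is.numeric(v)) return("intensities must be numeric")
  if (any(!is.finite(v))) return("intensities must all be finite")
  if (any(v < 0 | v > 1)) return("intensities must lie in [0, 1]")
  TRUE
})

#' Estimation pipeline configuration
#'
#' Tunable parameters of the detection/quantification pipeline and the
#' geometric direction estimator. See [pipelineConfig()] for defaults and
#' the meaning of each parameter.
#'
#' @slot alpha EMA smoothing coefficient in (0, 1].
#' @slot tauRope origin-retention threshold fraction in (0, 1].
#' @slot tauMaq displacement plausibility threshold in pixels (> 0).
#' @slot beta reliability boost factor (> 0).
#' @slot minProminence peak prominence threshold as a fraction of the
#'   zero-lag self-similarity value, in (0, 1).
#' @slot cropSide side of the square analysis window in pixels.
#' @slot epsilonParallel determinant cutoff for the parallel-ray fallback.
#' @slot lagMapping strategy converting peak lags to candidate positions.
#' @slot backgroundThreshold intensity below which a pixel counts as object.
#' @slot diagFraction minimum diagonal length (fraction of the crop side)
#'   retained in the diagonal scanline matrices.
#' @slot convention coordinate/angle convention tag.
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(
    alpha = "numeric", tauRope = "numeric", tauMaq = "numeric",
    beta = "numeric", minProminence = "numeric", cropSide = "numeric",
    epsilonParallel = "numeric", lagMapping = "character",
    backgroundThreshold = "numeric", diagFraction = "numeric",
    convention = "character"
  )
)

setValidity("PipelineConfig", function(object) {
  msg <- character()
  chk <- function(val, lo, hi, name, lo.open = TRUE, hi.open = FALSE) {
    ok <- is.finite(val) &&
      (if (lo.open) val > lo else val >= lo) &&
      (if (hi.open) val < hi else val <= hi)
    if (!ok) msg <<- c(msg, sprintf("%s must lie in %s%g, %g%s", name,
      if (lo.open) "(" else "[", lo, hi, if (hi.open) ")" else "]"))
  }
  chk(object@alpha, 0, 1, "alpha")
  chk(object@tauRope, 0, 1, "tauRope")
  chk(object@tauMaq, 0, Inf, "tauMaq", hi.open = TRUE)
  chk(object@beta, 0, Inf, "beta", hi.open = TRUE)
  chk(object@minProminence, 0, 1, "minProminence", hi.open = TRUE)
  chk(object@cropSide, 8, Inf, "cropSide", lo.open = FALSE, hi.open = TRUE)
  chk(object@epsilonParallel, 0, 1, "epsilonParallel")
  chk(object@backgroundThreshold, 0, 1, "backgroundThreshold")
  chk(object@diagFraction, 0, 1, "diagFraction")
  if (!object@lagMapping %in% c("origin-centered"))
    msg <- c(msg, "lagMapping must be 'origin-centered'")
  if (length(msg)) msg else TRUE
})

#' Per-direction stack of scanlines
#'
#' Scanlines extracted from a centered square frame along one of the four
#' principal directions. Horizontal rows are the image rows verbatim;
#' vertical rows are the rows of the 90-degree-rotated image; diagonal row k
#' collects the pixels with i + j = k and antidiagonal row k those with
#' j - i + M = k (i = row, j = column), each center-aligned and padded with
#' its own edge values to a common length.
#'
#' @slot direction one of "horizontal", "diagonal", "vertical", "antidiagonal".
#' @slot values K x L matrix, one scanline per row.
#' @slot cropWindow range (first, last) of the retained diagonal indices k;
#'   for horizontal/vertical this is simply c(1, K).
#' @exportClass DirectionalMatrix
setClass("DirectionalMatrix",
  representation(direction = "character", values = "matrix", cropWindow = "integer")
)

#' Row-normalized scanline matrix
#'
#' Each valid row has mean 0 and population standard deviation 1; rows whose
#' spread is below 1e-12 are emitted as all zeros and flagged invalid.
#'
#' @slot values K x L matrix of z-scored scanlines.
#' @slot validRowMask logical, TRUE for rows with nonzero spread.
#' @exportClass NormalizedMatrix
setClass("NormalizedMatrix",
  representation(values = "matrix", validRowMask = "logical")
)

#' Normalized self-similarity profile of one scanline
#'
#' r[l] over lags -(N-1)..(N-1), with zero padding for out-of-range samples
#' and full-vector energies in the normalizer, so r[0] = 1 and |r| <= 1 for
#' any valid scanline.
#'
#' @slot lags integer lags.
#' @slot values correlation values r[l].
#' @slot valid FALSE when the scanline was all zeros.
#' @exportClass SelfSimilarityProfile
setClass("SelfSimilarityProfile",
  representation(lags = "integer", values = "numeric", valid = "logical")
)

#' Per-scanline artifact peak lags
#'
#' The lag of the second most prominent self-similarity peak per scanline
#' (NA when no nonzero-lag peak qualifies), plus the prominence it attained.
#' The complement set is the exact negation of the detected lags.
#'
#' @slot lags numeric vector of lags, NA for missing.
#' @slot prominences prominence of each detected peak (NA where missing).
#' @exportClass PeakLocations
setClass("PeakLocations",
  representation(lags = "numeric", prominences = "numeric")
)

#' Per-scanline reference origins
#'
#' Index of the dominant intensity transition per scanline (EMA-smoothed
#' maximum absolute slope), with origins failing the global threshold set
#' to NA.
#'
#' @slot origins numeric vector of origin indices, NA where not retained.
#' @slot maxSlopes per-scanline maximum absolute slope.
#' @slot threshold the global retention threshold actually used.
#' @exportClass ReferenceOrigins
setClass("ReferenceOrigins",
  representation(origins = "numeric", maxSlopes = "numeric", threshold = "numeric")
)

#' Quantified per-scanline artifact displacements
#'
#' Signed displacement between reference origin and the closest artifact
#' candidate position, with implausibly large values suppressed.
#'
#' @slot q numeric displacements in pixels (NA where missing or suppressed).
#' @slot status "valid", "missing" or "suppressed" per scanline.
#' @slot direction direction label of the parent scanline matrix.
#' @slot tauMaq the suppression threshold applied.
#' @exportClass MAQSet
setClass("MAQSet",
  representation(q = "numeric", status = "character", direction = "character",
                 tauMaq = "numeric")
)

#' Directional displacement statistics with reliability scores
#'
#' Mean and population standard deviation of the absolute valid displacements
#' per direction, the boosted deviations beta * sigma, and the reliability
#' scores obtained by the min-max / mid-mid swap (the most consistent
#' direction receives the largest score).
#'
#' @slot directions the four direction labels, fixed order.
#' @slot qbar mean absolute displacement per direction.
#' @slot sigma population standard deviation per direction.
#' @slot sigmaBoosted beta * sigma.
#' @slot reliability swapped reliability scores.
#' @slot nValid number of valid scanlines per direction.
#' @slot beta the boost factor used.
#' @exportClass DirectionalStats
setClass("DirectionalStats",
  representation(directions = "character", qbar = "numeric", sigma = "numeric",
                 sigmaBoosted = "numeric", reliability = "numeric",
                 nValid = "integer", beta = "numeric")
)

#' The eight-point 3D direction octagon
#'
#' Each direction and its complement mapped to a point (x, y, z) where the
#' x-y offset from the center is the directional mean displacement and z is
#' the reliability score. Points 5-8 are the central reflections of points
#' 1-4 with identical z.
#'
#' @slot points 8 x 3 numeric matrix, rows p1..p8.
#' @slot center the (x0, y0) mapping center.
#' @exportClass PointOctagon
setClass("PointOctagon",
  representation(points = "matrix", center = "numeric")
)

#' Selected circularly adjacent point triplet
#'
#' @slot indices the three circularly adjacent octagon indices.
#' @slot points 3 x 3 matrix of the selected points.
#' @slot totalDistance sum of the three origin distances.
#' @exportClass TripletSelection
setClass("TripletSelection",
  representation(indices = "integer", points = "matrix", totalDistance = "numeric")
)

#' Final direction estimate
#'
#' @slot theta estimated artifact direction in degrees, in [0, 360).
#' @slot thetaComplement (theta + 180) mod 360.
#' @slot q weighted artifact magnitude in pixels (>= 0).
#' @slot centerOfMass the 3D triplet center of mass.
#' @slot diagnostics list with per-direction statistics, the octagon, the
#'   selected triplet, segment index and boundary intersection point.
#' @seealso [estimateDirection()]
#' @exportClass DirectionEstimate
setClass("DirectionEstimate",
  representation(theta = "numeric", thetaComplement = "numeric", q = "numeric",
                 centerOfMass = "numeric", diagnostics = "list")
)

setValidity("DirectionEstimate", function(object) {
  msg <- character()
  if (object@theta < 0 || object@theta >= 360) msg <- c(msg, "theta must lie in [0, 360)")
  if (abs((object@theta + 180) %% 360 - object@thetaComplement) > 1e-9)
    msg <- c(msg, "thetaComplement must equal (theta + 180) mod 360")
  if (object@q < 0) msg <- c(msg, "q must be >= 0")
  if (length(msg)) msg else TRUE
})
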