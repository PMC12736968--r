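#' @include AllClasses.R config.R directional-prep.R mape.R rope.R maq.R made-geometry.R
NULL

#' Estimate movement artifact direction and magnitude from one frame
#'
#' Runs the full pipeline on a single grayscale frame: center-crop the dark
#' object, extract the four directional scanline matrices, z-normalize each
#' scanline, detect per-scanline artifact replica lags (self-similarity
#' peak prominence), locate reference origins (EMA slope maxima), quantify
#' per-scanline displacements with plausibility suppression, and fuse the
#' directional statistics through the 3D octagon / triplet / center-of-mass
#' geometry into a direction theta (degrees) and a weighted magnitude q
#' (pixels).
#'
#' Deterministic for fixed input and configuration. Errors with
#' "no object detected" on a blank frame and "no artifact signal" when no
#' direction yields any valid displacement (e.g. a sharp static object).
#'
#' @param image a numeric intensity matrix in [0, 1] or a
#'   [SyntheticFrame-class].
#' @param config a [PipelineConfig-class].
#' @return a [DirectionEstimate-class]; diagnostics retain the per-direction
#'   MAQ sets and statistics, the octagon, the selected triplet, the
#'   segment index and the boundary intersection.
#' @examples
#' fr <- renderObjectTrail(motionParameters(v = 0.24, phi = 90))
#' est <- estimateDirection(fr)
#' theta(est)
#' @export
estimateDirection <- function(image, config = pipelineConfig()) {
  img <- if (is(image, "SyntheticFrame")) image@intensities else image
  cropped <- cropCenter(img, side = config@cropSide,
                        threshold = config@backgroundThreshold)
  mats <- buildDirectionalMatrices(cropped, diagFraction = config@diagFraction)
  stages <- lapply(mats, function(dm) {
    norm <- normalizeRows(dm)
    peaks <- scanMatrix(norm, minProminence = config@minProminence)
    origins <- referenceOrigins(norm, alpha = config@alpha,
                                tauRope = config@tauRope)
    maq <- maqMatrix(origins, peaks, tauMaq = config@tauMaq,
                     direction = dm@direction, lagMapping = config@lagMapping)
    list(peaks = peaks, origins = origins, maq = maq)
  })
  maqSets <- lapply(stages, `[[`, "maq")
  stats <- directionalStats(maqSets, beta = config@beta)
  octagon <- mapPoints(stats)
  triplet <- selectTriplet(octagon)
  com <- centerOfMass(triplet)
  ang <- directionAngle(com)
  seg <- segmentIndex(ang$theta)
  edges <- neighborMatrix(octagon)
  inter <- raySegmentIntersection(ang$theta, edges[seg, ],
                                  epsilon = config@epsilonParallel)
  q <- weightedDistance(inter$point)
  new("DirectionEstimate", theta = ang$theta,
      thetaComplement = ang$thetaComplement, q = q,
      centerOfMass = as.numeric(com),
      diagnostics = list(maqSets = maqSets, stages = stages, stats = stats,
                         octagon = octagon, triplet = triplet,
                         segmentIndex = seg, intersection = inter,
                         configDigest = configDigest(config)))
}

#' Dump per-scanline pipeline diagnostics as CSV
#'
#' Writes one CSV per direction (\code{<prefix>-<direction>.csv}) with the
#' per-scanline outputs of every pipeline stage: replica lag and prominence,
#' reference origin, maximum slope and retained flag, and the quantified
#' displacement with its status.
#'
#' @param estimate a [DirectionEstimate-class] from [estimateDirection()].
#' @param prefix path prefix for the output files.
#' @return the written paths, invisibly.
#' @export
writeDiagnostics <- function(estimate, prefix) {
  stages <- estimate@diagnostics$stages
  paths <- character()
  for (nm in names(stages)) {
    st <- stages[[nm]]
    df <- data.frame(
      row = seq_along(st$maq@q),
      lag = st$peaks@lags,
      prominence = st$peaks@prominences,
      origin = st$origins@origins,
      max_slope = st$origins@maxSlopes,
      retained = !is.na(st$origins@origins),
      q = st$maq@q,
      status = st$maq@status)
    path <- paste0(prefix, "-", nm, ".csv")
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Directional MAQ response over an orientation x velocity grid
#'
#' For each grid cell, simulates one object-trail frame and records the mean
#' absolute valid displacement of every direction — the per-direction
#' response map showing each scanline family peaking at its own orientation.
#'
#' @param phis orientations in degrees.
#' @param vs velocities in m/s.
#' @param common a [MotionParameters-class] supplying the non-(phi, v)
#'   parameters.
#' @param objectRadius dark disk radius in pixels.
#' @param shape simulated frame dimensions.
#' @param config a [PipelineConfig-class].
#' @param csv optional output path for the long-format table.
#' @return data.frame with columns phi, v, direction, mean_abs_q, n_valid.
#' @export
directionalResponseGrid <- function(phis, vs, common = motionParameters(),
                                    objectRadius = 2, shape = c(256, 256),
                                    config = pipelineConfig(), csv = NULL) {
  rows <- list()
  for (v in vs) for (phi in phis) {
    p <- motionParameters(A = common@A, omega = common@omega, v = v,
                          phi = phi, exposure = common@exposure,
                          step = common@step,
                          pixelsPerMeter = common@pixelsPerMeter)
    fr <- renderObjectTrail(p, objectRadius = objectRadius, shape = shape)
    est <- tryCatch(estimateDirection(fr, config), error = function(e) NULL)
    for (d in seq_len(4)) {
      nm <- c("horizontal", "diagonal", "vertical", "antidiagonal")[d]
      qv <- if (is.null(est)) numeric() else
        abs(validQ(est@diagnostics$maqSets[[d]]))
      rows[[length(rows) + 1]] <- data.frame(
        phi = phi, v = v, direction = nm,
        mean_abs_q = if (length(qv)) mean(qv) else NA_real_,
        n_valid = length(qv))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(out, csv, row.names = FALSE,
                                      quote = FALSE)
  out
}
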