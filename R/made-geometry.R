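#' @include AllClasses.R maq.R
NULL

.directionOrder <- c("horizontal", "diagonal", "vertical", "antidiagonal")

#' Directional displacement statistics
#'
#' Mean and population standard deviation of the absolute valid
#' displacements per direction. Absolute values are used because the
#' octagon mapping places +/- qbar symmetrically, which presumes a
#' nonnegative magnitude. A direction with no valid displacement gets
#' qbar = 0 and a pre-swap deviation of ten times the largest finite
#' deviation among the others (with a floor of one, in case every populated
#' direction has zero dispersion), so the reliability swap assigns it the
#' lowest score.
#'
#' @param maqSets named list of four [MAQSet-class] objects in the order
#'   horizontal, diagonal, vertical, antidiagonal.
#' @param beta boost factor applied to the deviations before the swap.
#' @return a [DirectionalStats-class].
#' @export
directionalStats <- function(maqSets, beta = 1) {
  if (beta <= 0) stop("beta must be > 0")
  if (length(maqSets) != 4L) stop("expected four directional MAQ sets")
  qbar <- numeric(4); sigma <- rep(NA_real_, 4); nValid <- integer(4)
  for (d in 1:4) {
    qv <- abs(validQ(maqSets[[d]]))
    nValid[d] <- length(qv)
    if (length(qv)) {
      qbar[d] <- mean(qv)
      sigma[d] <- sqrt(mean((qv - mean(qv))^2))
    }
  }
  if (all(is.na(sigma))) stop("no artifact signal")
  # floor of 1 keeps empty directions strictly below the others even when
  # every populated direction has zero dispersion
  sigma[is.na(sigma)] <- max(10 * max(sigma, na.rm = TRUE), 1)
  boosted <- beta * sigma
  new("DirectionalStats", directions = .directionOrder, qbar = qbar,
      sigma = sigma, sigmaBoosted = boosted,
      reliability = reliabilitySwap(boosted), nValid = nValid, beta = beta)
}

#' Reliability swap of the boosted deviations
#'
#' Lower dispersion means more consistent, hence more reliable,
#' measurements; the swap inverts the order of significance so the
#' direction with the smallest boosted deviation receives the largest value
#' and vice versa, with the two middle values exchanged. Ties are resolved
#' by the stable input order (horizontal, diagonal, vertical,
#' antidiagonal). Applying the swap twice restores the input.
#'
#' @param sigmasBoosted four finite values.
#' @return four reliability scores (a permutation of the input).
#' @export
reliabilitySwap <- function(sigmasBoosted) {
  if (length(sigmasBoosted) != 4L || any(!is.finite(sigmasBoosted)))
    stop("expected four finite values")
  ord <- order(sigmasBoosted)          # stable: ties keep input order
  out <- numeric(4)
  sorted <- sigmasBoosted[ord]
  out[ord] <- sorted[4:1]
  out
}

#' Map directional statistics to the 3D point octagon
#'
#' Each direction and its complement become one of eight 3D points: the x-y
#' offset from the center is the directional mean displacement (diagonal
#' directions offset on both axes), and z is the reliability score.
#' Points 5-8 are the central reflections of points 1-4.
#'
#' @param stats a [DirectionalStats-class].
#' @param center the (x0, y0) mapping center; the default (0, 0) places the
#'   octagon around the origin that the triplet selection and the weighted
#'   distance measure from.
#' @return a [PointOctagon-class].
#' @export
mapPoints <- function(stats, center = c(0, 0)) {
  q <- stats@qbar; z <- stats@reliability
  x0 <- center[1]; y0 <- center[2]
  pts <- rbind(
    c(x0 + q[1], y0,        z[1]),   # horizontal
    c(x0 + q[2], y0 + q[2], z[2]),   # diagonal
    c(x0,        y0 + q[3], z[3]),   # vertical
    c(x0 - q[4], y0 + q[4], z[4]),   # antidiagonal
    c(x0 - q[1], y0,        z[1]),
    c(x0 - q[2], y0 - q[2], z[2]),
    c(x0,        y0 - q[3], z[3]),
    c(x0 + q[4], y0 - q[4], z[4])
  )
  new("PointOctagon", points = pts, center = as.numeric(center))
}

#' Select the circularly adjacent triplet farthest from the origin
#'
#' Enumerates the eight circular adjacent triplets (i, i+1, i+2 with
#' wrap-around), sums the 3D Euclidean distances of their points from the
#' origin, and returns the triplet maximizing the total; ties go to the
#' smallest starting index.
#'
#' @param octagon a [PointOctagon-class].
#' @return a [TripletSelection-class].
#' @export
selectTriplet <- function(octagon) {
  P <- octagon@points
  n <- nrow(P)
  d <- sqrt(rowSums(P^2))
  idx <- function(i) c(i, i %% n + 1, (i + 1) %% n + 1)
  sums <- vapply(seq_len(n), function(i) sum(d[idx(i)]), numeric(1))
  best <- which.max(sums)   # first maximum = smallest starting index
  ind <- as.integer(idx(best))
  new("TripletSelection", indices = ind, points = P[ind, , drop = FALSE],
      totalDistance = sums[best])
}

#' Center of mass of a point triplet
#'
#' @param triplet a [TripletSelection-class] or a 3 x 3 numeric matrix.
#' @return numeric length-3 vector (x, y, z).
#' @export
centerOfMass <- function(triplet) {
  m <- if (is(triplet, "TripletSelection")) triplet@points else triplet
  colMeans(m)
}

#' Direction angle of a 3D point's x-y projection
#'
#' Four-quadrant angle of (Cx, Cy) from the +x axis, normalized to
#' [0, 360), with the complement 180 degrees away.
#'
#' @param C numeric vector with at least (x, y).
#' @return list(theta, thetaComplement) in degrees.
#' @export
directionAngle <- function(C) {
  if (C[1] == 0 && C[2] == 0) stop("degenerate center of mass")
  th <- atan2(C[2], C[1]) * 180 / pi
  th <- th %% 360
  list(theta = th, thetaComplement = (th + 180) %% 360)
}

#' Circular edge list of the octagon
#'
#' Edge i connects point i to point i+1, with the final edge wrapping back
#' to point 1, closing the polygon boundary.
#'
#' @param octagon a [PointOctagon-class].
#' @return an 8 x 6 matrix; row i holds the start point (x, y, z) followed
#'   by the end point (x, y, z) of edge i.
#' @export
neighborMatrix <- function(octagon) {
  P <- octagon@points
  n <- nrow(P)
  nxt <- seq_len(n) %% n + 1
  cbind(P, P[nxt, , drop = FALSE])
}

#' Angular segment index for a direction
#'
#' The 360-degree circle is divided into eight 45-degree segments matching
#' the polygon edges; the index is floor(theta / 45) + 1, with theta = 360
#' wrapping back to segment 1.
#'
#' @param theta angle in degrees, in [0, 360].
#' @return integer segment index in 1..8.
#' @export
segmentIndex <- function(theta) {
  if (theta < 0 || theta > 360) stop("theta must lie in [0, 360]")
  i <- floor(theta / 45) + 1
  if (i > 8) 1L else as.integer(i)
}

#' Intersection of the direction ray with a polygon edge
#'
#' Solves the 2x2 parametric system equating the ray from the origin along
#' (cos theta, sin theta) with the edge's segment parameterization. When
#' the determinant magnitude falls below \code{epsilon} (near-parallel),
#' the segment midpoint (s = 0.5) is used as a fallback; otherwise s is
#' clamped to [0, 1] so the intersection stays on the segment. The 3D point
#' is interpolated linearly between the edge endpoints (z included).
#'
#' @param theta ray direction in degrees.
#' @param edge numeric length-6 vector: start (x, y, z) then end (x, y, z).
#' @param epsilon determinant cutoff for the parallel fallback.
#' @return list(point = numeric 3, s = clamped parameter, t = ray parameter
#'   or NA under the fallback).
#' @export
raySegmentIntersection <- function(theta, edge, epsilon = 1e-10) {
  ps <- edge[1:3]; pe <- edge[4:6]
  d <- c(cos(theta * pi / 180), sin(theta * pi / 180))
  e <- pe[1:2] - ps[1:2]
  A <- matrix(c(d[1], d[2], -e[1], -e[2]), 2, 2)
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < epsilon) {
    s <- 0.5
    t <- NA_real_
  } else {
    sol <- solve(A, ps[1:2])
    t <- sol[1]
    s <- max(0, min(1, sol[2]))
  }
  list(point = ps + s * (pe - ps), s = s, t = t)
}

#' Weighted artifact magnitude
#'
#' 3D Euclidean distance of the boundary intersection point from the
#' origin; the reliability coordinate participates in the norm.
#'
#' @param point numeric length-3 vector.
#' @return nonnegative scalar.
#' @export
weightedDistance <- function(point) {
  sqrt(sum(point^2))
}
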