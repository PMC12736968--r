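maqOf <- function(q, direction = "horizontal") {
  status <- ifelse(is.na(q), "suppressed", "valid")
  new("MAQSet", q = as.numeric(q), status = status, direction = direction,
      tauMaq = 112)
}
fourSets <- function(h, d, v, a) list(maqOf(h), maqOf(d, "diagonal"),
                                      maqOf(v, "vertical"),
                                      maqOf(a, "antidiagonal"))

test_that("directional statistics use absolute valid displacements", {
  st <- directionalStats(fourSets(c(2, 2, 2), c(1, 3), c(-1, -3), 5), beta = 2)
  expect_equal(st@qbar, c(2, 2, 2, 5))
  expect_equal(st@sigma, c(0, 1, 1, 0))
  expect_equal(st@sigmaBoosted, c(0, 2, 2, 0))
  expect_equal(st@nValid, c(3L, 2L, 2L, 1L))
})

test_that("an empty direction falls to the lowest reliability", {
  st <- directionalStats(fourSets(c(4, 8), c(1, 3), c(2, 2), NA))
  expect_equal(st@qbar[4], 0)
  expect_equal(st@sigma[4], 10 * 2)  # ten times the largest finite sigma
  expect_equal(st@reliability[4], min(st@reliability))
  expect_error(directionalStats(fourSets(NA, NA, NA, NA)),
               "no artifact signal")
})

test_that("the reliability swap inverts the order of significance", {
  expect_equal(reliabilitySwap(c(4, 3, 2, 1)), c(1, 2, 3, 4))
  expect_equal(reliabilitySwap(c(7, 7, 7, 7)), c(7, 7, 7, 7))
  set.seed(41)
  for (i in 1:20) {
    s <- sort(runif(4))[sample(4)]  # distinct values, random order
    expect_equal(reliabilitySwap(reliabilitySwap(s)), s)  # involution
    expect_equal(which.min(reliabilitySwap(s)), which.max(s))
    expect_equal(which.max(reliabilitySwap(s)), which.min(s))
  }
})

statsOf <- function(qbar, rel) {
  new("DirectionalStats", directions = c("horizontal", "diagonal",
      "vertical", "antidiagonal"), qbar = qbar, sigma = rel,
      sigmaBoosted = rel, reliability = rel, nValid = rep(1L, 4), beta = 1)
}

test_that("the octagon follows the published point layout", {
  oct <- mapPoints(statsOf(rep(1, 4), rep(0, 4)))
  expected <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 0), c(-1, 1, 0),
                    c(-1, 0, 0), c(-1, -1, 0), c(0, -1, 0), c(1, -1, 0))
  expect_equal(oct@points, expected, ignore_attr = TRUE)

  set.seed(42)
  oct2 <- mapPoints(statsOf(runif(4), runif(4)))
  for (i in 1:4) {
    expect_equal(oct2@points[i + 4, 1:2], -oct2@points[i, 1:2],
                 ignore_attr = TRUE)
    expect_equal(oct2@points[i + 4, 3], oct2@points[i, 3])
  }

  octZero <- mapPoints(statsOf(rep(0, 4), c(1, 2, 3, 4)))
  expect_true(all(octZero@points[, 1:2] == 0))
})

test_that("triplet selection maximizes total origin distance with ties to the smallest start", {
  octEq <- mapPoints(statsOf(rep(1, 4), rep(0, 4)))
  # all eight corner distances... diagonals differ; build truly equidistant points
  pts <- t(vapply(seq(0, 315, 45), function(a)
    c(cos(a * pi / 180), sin(a * pi / 180), 0), numeric(3)))
  octRound <- new("PointOctagon", points = pts, center = c(0, 0))
  expect_equal(selectTriplet(octRound)@indices, c(1L, 2L, 3L))

  # distances (1,1,1,1,1,10,1,1): starts 4, 5, 6 tie; smallest start wins
  pts2 <- cbind(c(1, 1, 1, 1, 1, 10, 1, 1), 0, 0)
  octDom <- new("PointOctagon", points = pts2, center = c(0, 0))
  tri <- selectTriplet(octDom)
  expect_equal(tri@indices, c(4L, 5L, 6L))
  expect_equal(tri@totalDistance, 12)
})

test_that("triplet selection matches exhaustive enumeration on random octagons", {
  set.seed(43)
  for (i in 1:1000) {
    pts <- matrix(runif(24, -5, 5), 8, 3)
    oct <- new("PointOctagon", points = pts, center = c(0, 0))
    tri <- selectTriplet(oct)
    oracle <- bruteTriplet(pts)
    expect_identical(tri@indices, as.integer(oracle$indices))
    expect_equal(tri@totalDistance, oracle$total)
  }
})

test_that("center of mass averages the triplet", {
  m <- rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0))
  expect_equal(centerOfMass(m), c(1, 1, 0))
  p <- c(2, -1, 4)
  expect_equal(centerOfMass(rbind(p, p, p)), p, ignore_attr = TRUE)
  t0 <- c(1, 2, 3)
  expect_equal(centerOfMass(sweep(m, 2, t0, "+")), centerOfMass(m) + t0)
})

test_that("the direction angle covers all quadrants and axes", {
  expect_equal(directionAngle(c(1, 0))$theta, 0)
  expect_equal(directionAngle(c(1, 0))$thetaComplement, 180)
  expect_equal(directionAngle(c(0, 1))$theta, 90)
  expect_equal(directionAngle(c(-1, 0))$theta, 180)
  expect_equal(directionAngle(c(0, -1))$theta, 270)
  expect_equal(directionAngle(c(-1, -1))$theta, 225)
  expect_equal(directionAngle(c(1, -1))$theta, 315)
  expect_error(directionAngle(c(0, 0)), "degenerate")
})

test_that("the neighbor matrix closes the polygon", {
  set.seed(44)
  oct <- mapPoints(statsOf(runif(4, 1, 3), runif(4)))
  edges <- neighborMatrix(oct)
  expect_equal(dim(edges), c(8L, 6L))
  expect_equal(edges[8, 4:6], oct@points[1, ], ignore_attr = TRUE)
  for (i in 1:8) {
    expect_equal(edges[i, 1:3], oct@points[i, ], ignore_attr = TRUE)
    expect_equal(edges[i, 4:6], oct@points[i %% 8 + 1, ], ignore_attr = TRUE)
  }
})

test_that("segment indexing splits the circle into eight 45-degree bins", {
  expect_equal(segmentIndex(0), 1L)
  expect_equal(segmentIndex(44.999), 1L)
  expect_equal(segmentIndex(45), 2L)
  expect_equal(segmentIndex(100), 3L)
  expect_equal(segmentIndex(359.9), 8L)
  expect_equal(segmentIndex(360), 1L)
  expect_error(segmentIndex(-1), "theta")
  expect_error(segmentIndex(361), "theta")
})

test_that("ray-segment intersection solves, falls back and clamps", {
  hit <- raySegmentIntersection(0, c(2, -1, 0.5, 2, 1, 0.5))
  expect_equal(hit$point, c(2, 0, 0.5))
  expect_equal(hit$s, 0.5)
  expect_equal(hit$t, 2)

  par <- raySegmentIntersection(0, c(1, 1, 0, 3, 1, 0))  # parallel edge
  expect_equal(par$point, c(2, 1, 0))
  expect_equal(par$s, 0.5)

  clamp <- raySegmentIntersection(0, c(2, 1, 0, 2, 3, 0))  # unclamped s = -0.5
  expect_equal(clamp$s, 0)
  expect_equal(clamp$point, c(2, 1, 0))
})

test_that("intersections agree with dense segment sampling", {
  set.seed(45)
  n <- 10000
  sgrid <- seq(0, 1, length.out = n)
  hits <- 0
  for (i in 1:60) {
    theta <- runif(1, 0, 360)
    ps <- c(runif(2, -3, 3), runif(1))
    pe <- c(runif(2, -3, 3), runif(1))
    res <- raySegmentIntersection(theta, c(ps, pe))
    # the returned point always lies exactly on the segment
    expect_equal(res$point, ps + res$s * (pe - ps), tolerance = 1e-12)
    # forward intersections inside the segment lie exactly on the ray, and
    # dense sampling locates the same point
    if (!is.na(res$t) && res$t >= 0 && res$s > 0 && res$s < 1) {
      hits <- hits + 1
      expect_lt(distToRay(res$point[1:2], theta), 1e-9)
      samples <- outer(sgrid, pe[1:2] - ps[1:2]) +
        matrix(ps[1:2], n, 2, byrow = TRUE)
      dists <- vapply(seq_len(n), function(k)
        distToRay(samples[k, ], theta), numeric(1))
      expect_lte(abs(sgrid[which.min(dists)] - res$s), 1.5 / n)
    }
  }
  expect_gt(hits, 5)  # the branch was actually exercised
})

test_that("weighted distance is the 3D origin norm", {
  expect_equal(weightedDistance(c(3, 4, 0)), 5)
  expect_equal(weightedDistance(c(0, 0, 0)), 0)
  set.seed(46)
  p <- c(runif(2), 0.7)
  for (a in runif(5, 0, 2 * pi)) {
    rot <- c(cos(a) * p[1] - sin(a) * p[2], sin(a) * p[1] + cos(a) * p[2], p[3])
    expect_equal(weightedDistance(rot), weightedDistance(p))
  }
})

test_that("magnitude stays within the polygon boundary's distance range", {
  # the chord interior dips below the vertex distances (a regular octagon's
  # mid-edge sits at the inradius), so the true bounds are the minimum over
  # the selected edge and the maximum vertex distance
  set.seed(47)
  sgrid <- seq(0, 1, length.out = 2000)
  for (i in 1:20) {
    st <- statsOf(runif(4, 0.5, 4), rep(0.3, 4))
    oct <- mapPoints(st)
    dmax <- max(sqrt(rowSums(oct@points^2)))
    for (theta in seq(0, 355, by = 20)) {
      seg <- segmentIndex(theta)
      edge <- neighborMatrix(oct)[seg, ]
      inter <- raySegmentIntersection(theta, edge)
      q <- weightedDistance(inter$point)
      edgePts <- outer(sgrid, edge[4:6] - edge[1:3]) +
        matrix(edge[1:3], length(sgrid), 3, byrow = TRUE)
      edgeMin <- min(sqrt(rowSums(edgePts^2)))
      expect_gte(q, edgeMin - 1e-6)
      expect_lte(q, dmax + 1e-9)
    }
  }

  # regular octagon with equal reliabilities: q between inradius and vertex
  # radius for every direction
  reg <- mapPoints(statsOf(c(1, sqrt(0.5), 1, sqrt(0.5)), rep(0, 4)))
  for (theta in seq(0, 359, by = 7)) {
    seg <- segmentIndex(theta)
    q <- weightedDistance(
      raySegmentIntersection(theta, neighborMatrix(reg)[seg, ])$point)
    expect_gte(q, cos(pi / 8) - 1e-9)
    expect_lte(q, 1 + 1e-9)
  }
})
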