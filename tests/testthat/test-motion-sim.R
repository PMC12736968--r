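test_that("trajectory matches its closed form", {
  p0 <- motionParameters(A = 0, v = 0)
  for (t in c(0, 0.25, 1)) expect_equal(unname(trajectory(p0, t)[1, ]), c(0, 0))

  p1 <- motionParameters(A = 1, omega = pi / 2, v = 0)
  expect_equal(unname(trajectory(p1, 1)[1, ]), c(0, 1), tolerance = 1e-12)

  p2 <- motionParameters(A = 1, omega = 1, v = 0.1, phi = 0,
                         exposure = 2, pixelsPerMeter = 100)
  expect_equal(unname(trajectory(p2, 2)[1, ]), c(cos(2) - 20, sin(2)),
               tolerance = 1e-12)

  expect_error(trajectory(p1, 1.5), "within")
  expect_error(trajectory(p1, -0.1), "within")
})

test_that("arc length reduces to the closed forms in the pure limits", {
  pOsc <- motionParameters(A = 3, omega = 2 * pi, v = 0, exposure = 1.5)
  expect_equal(arcLength(pOsc), 3 * 2 * pi * 1.5, tolerance = 1e-6)

  pDrift <- motionParameters(A = 0, v = 0.4, exposure = 2, pixelsPerMeter = 50)
  expect_equal(arcLength(pDrift), 0.4 * 50 * 2, tolerance = 1e-6)
})

test_that("arc length agrees with a fine Riemann-sum oracle", {
  p <- motionParameters(A = 1, omega = 1, v = 1, phi = 0,
                        exposure = 2 * pi, pixelsPerMeter = 1)
  h <- 1e-5
  tm <- seq(h / 2, p@exposure - h / 2, by = h)
  # midpoint speeds from symmetric finite differences of the trajectory itself
  rp <- trajectory(p, pmin(p@exposure, tm + h / 2))
  rm <- trajectory(p, pmax(0, tm - h / 2))
  speed <- sqrt(rowSums((rp - rm)^2)) / h
  oracle <- sum(speed) * h
  expect_equal(arcLength(p), oracle, tolerance = 1e-4)
})

test_that("point trail rendering places and conserves kernel mass", {
  pStill <- motionParameters(A = 0, v = 0, step = 1e-2)
  fr <- renderPointTrail(pStill, psfSpec("delta"), shape = c(65, 65))
  nz <- which(intensities(fr) > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1L)
  expect_equal(unname(nz[1, ]), c(33, 33))  # the geometric frame center

  pDrift <- motionParameters(A = 0, v = 0.3, phi = 0, step = 1e-3,
                             pixelsPerMeter = 100)
  fr2 <- renderPointTrail(pDrift, psfSpec("delta"), shape = c(65, 65))
  expect_equal(fr2@meta$totalMass, nSamples(pDrift))  # conservation
  nz2 <- which(intensities(fr2) > 0, arr.ind = TRUE)
  expect_equal(length(unique(nz2[, "row"])), 1L)
  expect_equal(length(unique(nz2[, "col"])), 31L)  # 30 px drift spans 31 cols
})

test_that("object trail renders a swept dark disk on white", {
  pStill <- motionParameters(A = 0, v = 0, step = 1e-2)
  fr <- renderObjectTrail(pStill, psfSpec("delta"), objectRadius = 5,
                          shape = c(65, 65))
  img <- intensities(fr)
  expect_equal(img[33, 33], 0)
  expect_equal(img[1, 1], 1)
  expect_equal(img[5, 60], 1)

  pDrift <- motionParameters(A = 0, v = 0.3, phi = 0, step = 1e-3,
                             pixelsPerMeter = 100)
  fr2 <- renderObjectTrail(pDrift, psfSpec("delta"), objectRadius = 10,
                           shape = c(97, 97))
  dark <- which(intensities(fr2) < 1, arr.ind = TRUE)
  expect_equal(diff(range(dark[, "col"])) + 1, 51)  # drift 30 + disk 21
  expect_equal(diff(range(dark[, "row"])) + 1, 21)
  expect_equal(fr2@truthPhi, 0)
  expect_equal(fr2@truthV, 0.3)

  expect_error(renderObjectTrail(pStill, objectRadius = 100, shape = c(65, 65)),
               "larger than the frame")
})

test_that("trail elongation along phi is non-decreasing in velocity", {
  widths <- vapply(c(0.08, 0.16, 0.24, 0.32), function(v) {
    fr <- renderObjectTrail(fastParams(v, 0), psfSpec("delta"),
                            objectRadius = 2, shape = c(128, 128))
    dark <- which(intensities(fr) < 1, arr.ind = TRUE)
    diff(range(dark[, "col"])) + 1
  }, numeric(1))
  expect_true(all(diff(widths) >= 0))
})

test_that("rendering is translation-consistent across frame sizes", {
  p <- fastParams(0.16, 0)
  f1 <- renderObjectTrail(p, psfSpec("delta"), objectRadius = 2,
                          shape = c(129, 129))
  f2 <- renderObjectTrail(p, psfSpec("delta"), objectRadius = 2,
                          shape = c(131, 131))
  d1 <- which(intensities(f1) < 1, arr.ind = TRUE)
  d2 <- which(intensities(f2) < 1, arr.ind = TRUE)
  # frame center moves from (65,65) to (66,66): support shifts by +1
  expect_equal(d2[order(d2[, 1], d2[, 2]), ] - 1L,
               d1[order(d1[, 1], d1[, 2]), ],
               ignore_attr = TRUE)
})

test_that("rotating phi by 90 degrees matches rotating the frame", {
  f0 <- renderObjectTrail(fastParams(0.24, 0), psfSpec("delta"),
                          objectRadius = 2, shape = c(129, 129))
  f90 <- renderObjectTrail(fastParams(0.24, 90), psfSpec("delta"),
                           objectRadius = 2, shape = c(129, 129))
  b0 <- which(rotate90(intensities(f0)) < 1, arr.ind = TRUE)
  b90 <- which(intensities(f90) < 1, arr.ind = TRUE)
  # supports agree within the 1 px tolerance of the rounding rule
  expect_lte(max(abs(range(b0[, 1]) - range(b90[, 1]))), 1)
  expect_lte(max(abs(range(b0[, 2]) - range(b90[, 2]))), 1)
})

test_that("fixture grids are complete, labeled and deterministic", {
  common <- motionParameters(step = 5e-3, pixelsPerMeter = 40)
  phis <- c(0, 45, 90)
  vs <- c(0.1, 0.2)
  g1 <- makeFixtureGrid(phis, vs, common, psfSpec("delta"),
                        objectRadius = 2, shape = c(64, 64))
  g2 <- makeFixtureGrid(phis, vs, common, psfSpec("delta"),
                        objectRadius = 2, shape = c(64, 64))
  expect_length(g1, 6L)
  expect_equal(vapply(g1, truthPhi, numeric(1)), rep(phis, times = 2))
  expect_equal(vapply(g1, truthV, numeric(1)), rep(vs, each = 3))
  for (k in seq_along(g1))
    expect_identical(intensities(g1[[k]]), intensities(g2[[k]]))
  expect_error(makeFixtureGrid(numeric(), vs, common), "nonempty")
})

test_that("optional additive noise is seeded and bounded", {
  p <- fastParams(0.2, 0)
  f1 <- renderObjectTrail(p, objectRadius = 2, shape = c(96, 96),
                          noiseSd = 0.05, noiseSeed = 7)
  f2 <- renderObjectTrail(p, objectRadius = 2, shape = c(96, 96),
                          noiseSd = 0.05, noiseSeed = 7)
  f3 <- renderObjectTrail(p, objectRadius = 2, shape = c(96, 96),
                          noiseSd = 0.05, noiseSeed = 8)
  expect_identical(intensities(f1), intensities(f2))
  expect_false(identical(intensities(f1), intensities(f3)))
  expect_true(all(intensities(f1) >= 0 & intensities(f1) <= 1))
})

test_that("parameter validity is enforced", {
  expect_error(motionParameters(A = -1), "A must")
  expect_error(motionParameters(step = 2, exposure = 1), "step must")
  expect_error(psfSpec("gaussian", sigma = 0), "sigma must")
  expect_equal(motionParameters(phi = 370)@phi, 10)
})
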