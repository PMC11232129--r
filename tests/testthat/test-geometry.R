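test_that("shoelace area matches closed forms on regular shapes", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(polygonArea(sq), 1)                    # 100 mm2 = 1 cm2
  expect_equal(polygonArea(sq[4:1, ]), 1)             # orientation-free
  # regular hexagon, side s = 10 mm: area = 3*sqrt(3)/2 * s^2
  th <- 2 * pi * (0:5) / 6
  hex <- cbind(10 * cos(th), 10 * sin(th))
  expect_equal(polygonArea(hex), 3 * sqrt(3) / 2 * 100 / 100, tolerance = 1e-12)
  # many-sided polygon approximating a circle r = 15 mm
  circ <- circlePoints(r = 15, n = 720)
  expect_equal(polygonArea(circ), pi * 225 / 100, tolerance = 1e-4)
})

test_that("shoelace area agrees with the rasterization oracle on random convex polygons", {
  set.seed(41)
  for (i in 1:50) {
    p <- randomConvexPolygon(n = sample(8:16, 1), a = runif(1, 8, 16),
                             b = runif(1, 5, 12),
                             center = runif(2, -5, 5), rot = runif(1, 0, pi))
    expect_equal(polygonArea(p), oracleAreaRaster(p, h = 0.05),
                 tolerance = 0.005)
  }
})

test_that("polygonArea rejects degenerate and self-intersecting input", {
  expect_error(polygonArea(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  # self-crossing with non-zero net area (a symmetric bowtie nets to zero
  # and is caught as degenerate instead)
  crossed <- rbind(c(0, 0), c(10, 0), c(3, 8), c(7, 8))
  expect_error(polygonArea(crossed), "self-intersecting")
  expect_error(polygonArea(rbind(c(0, 0), c(1, NA), c(1, 1))), "non-finite")
})

test_that("polygonCentroid is the area centroid, not the vertex mean", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2))
  expect_equal(polygonCentroid(sq), c(1, 1))
  # L-shape: vertex mean differs from the area centroid
  L <- rbind(c(0, 0), c(4, 0), c(4, 1), c(1, 1), c(1, 4), c(0, 4))
  # two rectangles: 4x1 at centroid (2, .5) area 4; 1x3 at (.5, 2.5) area 3
  expect_equal(polygonCentroid(L),
               c((4 * 2 + 3 * 0.5) / 7, (4 * 0.5 + 3 * 2.5) / 7))
  expect_false(isTRUE(all.equal(polygonCentroid(L), colMeans(L))))
})

test_that("maxTransverseDiameter matches the exact convex-chord oracle", {
  set.seed(42)
  for (i in 1:25) {
    p <- randomConvexPolygon(n = sample(10:20, 1), a = runif(1, 10, 25),
                             b = runif(1, 6, 15), rot = runif(1, 0, pi))
    ang <- runif(1, 0, 2 * pi)
    axis <- c(cos(ang), sin(ang))
    got <- maxTransverseDiameter(p, axis, step = 0.1)
    want <- oracleMaxChordConvex(p, axis)
    expect_lte(abs(got - want) / want, 0.01)
    expect_lte(got, want + 1e-9)   # station scan can only undershoot
  }
})

test_that("maxTransverseDiameter on an axis-aligned ellipse returns the perpendicular axis", {
  e <- circlePoints(1, 720) %*% diag(c(20, 12))  # semiaxes 20 (x), 12 (y)
  expect_equal(maxTransverseDiameter(e, c(0, 1), step = 0.05), 40,
               tolerance = 1e-3)
  expect_equal(maxTransverseDiameter(e, c(1, 0), step = 0.05), 24,
               tolerance = 1e-3)
})

test_that("geometry is invariant under rigid motion and scales correctly", {
  set.seed(7)
  p <- randomConvexPolygon(n = 14, a = 18, b = 9)
  a0 <- polygonArea(p)
  d0 <- maxTransverseDiameter(p, c(0, 1), step = 0.1)
  ang <- 0.7
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  q <- sweep(p %*% R, 2, c(31.2, -14.9), `+`)
  expect_equal(polygonArea(q), a0, tolerance = 1e-10)
  # the axis must rotate with the shape
  axisRot <- as.numeric(c(0, 1) %*% R)
  expect_equal(maxTransverseDiameter(q, axisRot, step = 0.1), d0,
               tolerance = 1e-6)
  # scaling: area quadratic, diameter linear
  expect_equal(polygonArea(p * 3), 9 * a0, tolerance = 1e-10)
  expect_equal(maxTransverseDiameter(p * 3, c(0, 1), step = 0.1), 3 * d0,
               tolerance = 0.01)
})

test_that("longAxis points from the LA to the LV and rejects coincident centroids", {
  lv <- circlePoints(15, 64, center = c(0, 40))
  la <- circlePoints(10, 64, center = c(0, 0))
  ax <- longAxis(lv, la)
  expect_equal(ax$direction, c(0, 1))
  expect_equal(ax$lvCentroid, c(0, 40), tolerance = 1e-9)
  expect_error(longAxis(circlePoints(15, 64), circlePoints(10, 64)),
               "coincide")
})

test_that("crossSectionalArea implements the biplane-ellipse and single-plane rules", {
  expect_equal(crossSectionalArea(40, 40), pi * 40 * 40 / 4 / 100)
  expect_equal(crossSectionalArea(30, 50),
               crossSectionalArea(50, 30))           # view-symmetric
  expect_equal(crossSectionalArea(d4 = 40, mode = "single_plane"),
               crossSectionalArea(40, 40))
  expect_error(crossSectionalArea(40, mode = "biplane_ellipse"), "requires")
  expect_error(crossSectionalArea(-1, 40), "non-positive")
})

test_that("contourLength handles open and closed contours", {
  sq <- rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10))
  expect_equal(contourLength(sq, closed = FALSE), 30)
  expect_equal(contourLength(sq, closed = TRUE), 40)
  # semicircle r=10, 2001 points: length -> pi*10
  th <- seq(0, pi, length.out = 2001)
  expect_equal(contourLength(cbind(10 * cos(th), 10 * sin(th))), 10 * pi,
               tolerance = 1e-5)
})

test_that("areaCurves recovers the analytic areas of concentric phantom chambers", {
  # LV: half-ellipse (a=60, b=20) closed by the mitral line; LA: ellipse below.
  n <- 10
  scl <- seq(1, 0.85, length.out = n)
  lvF <- lapply(scl, function(s) {
    phi <- pi * (0:95) / 95
    cbind(20 * s * cos(phi), 60 * s * sin(phi))
  })
  laF <- lapply(scl, function(s) {
    phi <- 2 * pi * (0:95) / 96
    cbind(14 * cos(phi), -25 + 10 * sin(phi))
  })
  lv2 <- ContourSequence("P", "2ch", "LV_endo", lvF)
  la2 <- ContourSequence("P", "2ch", "LA_endo", laF)
  lv4 <- ContourSequence("P", "4ch", "LV_endo", lvF)
  la4 <- ContourSequence("P", "4ch", "LA_endo", laF)
  ac <- areaCurves(lv2, la2, lv4, la4)
  # max transverse diameter of the half-ellipse is the base, 2*b*s
  expect_equal(areas(ac$LV), pi * (20 * scl)^2 / 100, tolerance = 5e-3)
  expect_equal(areas(ac$LA), rep(pi * 14^2 / 100, n), tolerance = 5e-3)
  expect_equal(frameTimes(ac$LV)[1], 0)
  expect_equal(frameTimes(ac$LV)[n], 1000)
  expect_error(areaCurves(lv2, la2, mode = "biplane_ellipse"), "requires both")
  acs <- areaCurves(lv4ch = lv4, la4ch = la4, mode = "single_plane")
  expect_equal(areas(acs$LV), areas(ac$LV), tolerance = 1e-9)
})
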