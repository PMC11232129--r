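test_that("strainCurve implements the Lagrangian convention", {
  L <- c(100, 90, 80, 95, 100)
  s <- strainCurve(L)
  expect_equal(s, c(0, -10, -20, -5, 0))
  expect_equal(strainCurve(L, refFrame = 3), 100 * (L - 80) / 80)
  expect_equal(strainCurve(L * 7.3), s)      # scale invariance
  expect_error(strainCurve(c(100, 0, 80)), "positive")
  expect_error(strainCurve(L, refFrame = 9), "reference")
})

test_that("lvGls is the mean of the per-view strain minima", {
  l2 <- c(100, 85, 90, 100)   # min strain -15
  l4 <- c(120, 96, 110, 120)  # min strain -20
  expect_equal(lvGls(l2, l4), -17.5)
  expect_warning(g <- lvGls(lengths2ch = l2), "single view")
  expect_equal(as.numeric(g), -15)
  expect_true(attr(g, "single_view"))
  expect_error(lvGls(), "at least one view")
})

test_that("lvGcs averages mid-third slice perimeter strain", {
  # 9 slices: mid third is slices 4-6
  perim <- matrix(100, 9, 4)
  perim[4, ] <- c(100, 80, 90, 100)   # min -20
  perim[5, ] <- c(100, 90, 95, 100)   # min -10
  perim[6, ] <- c(100, 85, 92, 100)   # min -15
  perim[1, ] <- c(100, 10, 10, 10)    # outside mid third: ignored
  expect_equal(lvGcs(perim), -15)
  expect_equal(lvGcs(perim[4:6, , drop = FALSE], midThirdOnly = FALSE), -15)
})

test_that("lvGrs recovers thickening of an annulus phantom exactly", {
  # concentric circles: thickness th(t) known in closed form
  rEndo <- c(15, 12, 13, 15)
  rEpi <- c(23, 24, 23.5, 23)
  n <- length(rEndo)
  mk <- function(rv, ch) lapply(seq_len(5), function(k)
    ContourSequence("P", "sax", ch,
                    lapply(rv, function(r) circlePoints(r, 64)),
                    sliceLocation = k * 8, sliceThickness = 8))
  endo <- mk(rEndo, "LV_endo"); epi <- mk(rEpi, "LV_epi")
  th <- rEpi - rEndo
  expect_equal(lvGrs(endo, epi), max(100 * (th - th[1]) / th[1]),
               tolerance = 1e-6)
  # epicardium inside endocardium must be refused
  expect_error(lvGrs(endo, mk(rEndo - 1, "LV_epi")), "inside")
})

test_that("laPhasicStrain decomposes additively and validates event order", {
  s <- c(0, 10, 25, 30, 22, 15, 14, 5, 1)
  ph <- laPhasicStrain(s, tMax = 4, tPreA = 7)
  expect_equal(unname(ph["la_slr"]), 30)
  expect_equal(unname(ph["la_slc"]), 16)
  expect_equal(unname(ph["la_slb"]), 13)
  expect_equal(unname(ph["la_slc"] + ph["la_slb"] + ph["la_residual"]),
               unname(ph["la_slr"]))
  expect_error(laPhasicStrain(s, tMax = 1, tPreA = 7), "tMax")
  expect_error(laPhasicStrain(s, tMax = 4, tPreA = 3), "follow")
  expect_error(laPhasicStrain(s, tMax = 4, tPreA = 9), "final")
})

test_that("StrainResult enforces the additivity invariant", {
  ok <- StrainResult(c(lv_gls = -17, lv_gcs = -12, lv_grs = 50,
                       la_slr = 30, la_slc = 16, la_slb = 13,
                       la_residual = 1), tMax = 10, tPreA = 25)
  expect_s4_class(ok, "StrainResult")
  expect_error(StrainResult(c(la_slr = 30, la_slc = 20, la_slb = 13,
                              la_residual = 1), tMax = 10, tPreA = 25),
               "must equal")
})

test_that("reported-convention check: reservoir equals conduit plus booster", {
  # convention check against published-style phasic values: the reservoir
  # strain should equal conduit + booster up to rounding of the components
  expect_lte(abs(30.2 - (18.5 + 11.8)), 0.15)
  expect_lte(abs(24.1 - (11.8 + 12.2)), 0.15)
})

test_that("strains are recovered on a zero-noise synthetic subject", {
  p <- subjectParams(noise_sd = 0, n_frames = 36, seed = 3)
  ds <- generateSubject(p)
  rec <- analyzeSubject(ds)
  tr <- ds$groundTruth$true_strains
  expect_equal(rec$lv_gls, unname(tr["lv_gls"]), tolerance = 0.01)
  expect_equal(rec$lv_gcs, unname(tr["lv_gcs"]), tolerance = 0.01)
  expect_equal(rec$lv_grs, unname(tr["lv_grs"]), tolerance = 0.01)
  expect_equal(rec$la_slr, unname(tr["la_slr"]), tolerance = 0.01)
  expect_equal(rec$la_slc, unname(tr["la_slc"]), tolerance = 0.05)
  expect_equal(rec$la_slb, unname(tr["la_slb"]), tolerance = 0.05)
  # additivity of the measured decomposition
  expect_equal(rec$la_slc + rec$la_slb + rec$la_residual, rec$la_slr,
               tolerance = 1e-12)
})
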