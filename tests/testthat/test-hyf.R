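test_that("hydraulicForce on constant curves is the plain difference", {
  lv <- rep(12.9, 30); la <- rep(7.9, 30)
  expect_equal(hydraulicForce(lv, la, c(1, 30)), 5.0)
  expect_equal(hydraulicForce(la, lv, c(1, 30)), -5.0)   # sign preserved
})

test_that("hyfCurve identities hold exactly", {
  set.seed(5)
  lv <- runif(40, 8, 14); la <- runif(40, 5, 11)
  d <- hyfCurve(lv, la)
  expect_equal(d, -hyfCurve(la, lv), tolerance = 1e-15)        # antisymmetry
  expect_equal(hyfCurve(lv, la + 2.5), d - 2.5, tolerance = 1e-12) # offset
  w <- c(10, 20)
  expect_equal(hydraulicForce(lv, la + 2.5, w),
               hydraulicForce(lv, la, w) - 2.5, tolerance = 1e-12)
  expect_error(hyfCurve(lv, la[-1]), "frame counts")
  expect_error(hydraulicForce(lv, la, c(0, 10)), "window")
  expect_error(hydraulicForce(lv, la, c(35, 45)), "window")
})

test_that("detectDiastasis finds the programmed plateau within one frame", {
  for (seed in 1:4) {
    p <- subjectParams(noise_sd = 0, n_frames = 28 + 4 * seed, seed = seed,
                       filling_ratio = c(0.7, 1.0, 1.4, 2.0)[seed])
    ds <- generateSubject(p, sax = FALSE)
    det <- detectDiastasis(ds$groundTruth$true_lv_area_curve)
    tw <- ds$groundTruth$true_diastasis_window
    expect_lte(abs(det$window[1] - tw[1]), 1)
    expect_lte(abs(det$window[2] - tw[2]), 1)
    expect_length(det$qcFlags, 0)
    # e-peak precedes the window, a-peak follows it
    expect_lt(det$ePeakFrame, det$window[1])
    expect_gt(det$aPeakFrame, det$window[2])
  }
})

test_that("detectDiastasis flags degenerate inputs instead of guessing", {
  # monotone decreasing curve: no diastolic limb at all
  expect_error(detectDiastasis(seq(14, 8, length.out = 20)),
               class = "hyforce_qc_error")
  # E-wave only (no atrial kick): rises after the minimum and stays flat
  n <- 40
  a <- c(seq(13, 9, length.out = 14), seq(9.2, 13, length.out = 10),
         rep(13, 16))
  det <- detectDiastasis(a)
  expect_true("no_a_peak" %in% det$qcFlags)
  expect_equal(det$window[1], det$window[2])
})

test_that("theta = 0 collapses the window and sets the short_diastasis flag", {
  p <- subjectParams(noise_sd = 0, n_frames = 40, seed = 2)
  ds <- generateSubject(p, sax = FALSE)
  det <- detectDiastasis(ds$groundTruth$true_lv_area_curve, theta = 0)
  expect_true("short_diastasis" %in% det$qcFlags)
  expect_equal(det$window[1], det$window[2])
})

test_that("HyF and the diastasis window are stable under contour-level noise", {
  # jitter can fragment the quiet run, so the detected window may shrink;
  # it must stay inside the programmed plateau (+/- 2 frames) and the
  # scalar HyF must be essentially unchanged
  base <- subjectParams(noise_sd = 0, n_frames = 40, seed = 9)
  clean <- generateSubject(base, sax = FALSE)
  noisy <- generateSubject(subjectParams(noise_sd = 0.5, n_frames = 40,
                                         seed = 9), sax = FALSE)
  rec <- analyzeSubject(noisy$sequences)
  tw <- clean$groundTruth$true_diastasis_window
  expect_gte(rec$dia_start, tw[1] - 2)
  expect_lte(rec$dia_end, tw[2] + 2)
  recClean <- analyzeSubject(clean$sequences)
  expect_lt(abs(rec$hyf - recClean$hyf), 0.3)
})

test_that("hyfAnalysis recovers the programmed HyF on zero-noise subjects", {
  for (seed in c(1, 6)) {
    p <- subjectParams(noise_sd = 0, n_frames = 40, seed = seed)
    ds <- generateSubject(p, sax = FALSE)
    rec <- analyzeSubject(ds$sequences)
    expect_equal(rec$hyf, ds$groundTruth$true_hyf, tolerance = 0.01)
  }
})

test_that("hyfAnalysis returns a well-formed HyFResult", {
  p <- subjectParams(noise_sd = 0, n_frames = 40)
  ds <- generateSubject(p, sax = FALSE)
  ac <- areaCurves(ds$sequences$LV_endo_2ch, ds$sequences$LA_endo_2ch,
                   ds$sequences$LV_endo_4ch, ds$sequences$LA_endo_4ch)
  hy <- hyfAnalysis(ac$LV, ac$LA)
  expect_s4_class(hy, "HyFResult")
  expect_length(hy@diffCurve, nFrames(ac$LV))
  w <- diastasisWindow(hy)
  expect_equal(hyf(hy), mean(hy@diffCurve[w[1]:w[2]]))
  expect_output(show(hy), "HyFResult")
})
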