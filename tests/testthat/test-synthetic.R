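test_that("chamberWaveform has the programmed phase structure", {
  p <- subjectParams(n_frames = 50, noise_sd = 0)
  sLV <- chamberWaveform("LV", p)
  sLA <- chamberWaveform("LA", p)
  ph <- waveformPhases(p)
  # frame 1 is the reference scale; the curve is periodic
  expect_equal(sLV[1], 1); expect_equal(sLV[50], 1, tolerance = 1e-12)
  expect_equal(sLA[1], 1); expect_equal(sLA[50], 1, tolerance = 1e-12)
  # LV minimum at end-systole, LA maximum there (reciprocal chambers)
  expect_equal(which.min(sLV), ph$es_frame)
  expect_lte(abs(which.max(sLA) - which.min(sLV)), 1)
  # extrema to grid resolution (end-systole need not fall on a frame)
  expect_equal(min(sLV), 1 - p$lv_contraction, tolerance = 1e-3)
  expect_equal(max(sLA), 1 + p$la_reservoir, tolerance = 1e-3)
  # the plateau is exactly flat on both curves
  w <- ph$plateau_frames
  expect_gte(w[2] - w[1], 2)
  expect_equal(diff(sLV[w[1]:w[2]]), rep(0, w[2] - w[1]))
  expect_equal(diff(sLA[w[1]:w[2]]), rep(0, w[2] - w[1]))
  # filling_ratio splits diastolic LV refilling between E wave and kick
  r <- p$filling_ratio
  earlyGain <- sLV[w[1]] - min(sLV)
  lateGain <- sLV[p$n_frames] - sLV[w[2]]
  expect_equal(earlyGain / lateGain, r, tolerance = 2e-3)
})

test_that("subjectParams validates its inputs", {
  expect_error(subjectParams(n_frames = 6), "n_frames")
  expect_error(subjectParams(diastasis_fraction = 1.2), "diastasis_fraction")
  expect_error(subjectParams(filling_ratio = -1), "filling_ratio")
  expect_error(subjectParams(lv_contraction = 1.5), "lv_contraction")
  expect_error(subjectParams(noise_sd = -0.1), "noise_sd")
  expect_error(subjectParams(n_points = 20), "48")
})

test_that("zero-noise LA contours are exact ellipses with the programmed area", {
  p <- subjectParams(noise_sd = 0, n_frames = 32,
                     la_base_semiaxes = c(30, 20))
  ds <- generateSubject(p, sax = FALSE)
  sLA <- ds$groundTruth$la_scale
  for (f in c(1, 10, 25)) {
    a <- polygonArea(ds$sequences$LA_endo_2ch@frames[[f]])
    expect_equal(a, pi * 30 * 20 * sLA[f]^2 / 100, tolerance = 0.005)
  }
})

test_that("measured area curves match the analytic ground truth without noise", {
  p <- subjectParams(noise_sd = 0, n_frames = 36, seed = 4)
  ds <- generateSubject(p, sax = FALSE)
  ac <- areaCurves(ds$sequences$LV_endo_2ch, ds$sequences$LA_endo_2ch,
                   ds$sequences$LV_endo_4ch, ds$sequences$LA_endo_4ch)
  expect_equal(areas(ac$LV), ds$groundTruth$true_lv_area_curve,
               tolerance = 0.005)
  expect_equal(areas(ac$LA), ds$groundTruth$true_la_area_curve,
               tolerance = 0.005)
})

test_that("generation is deterministic for a fixed seed", {
  p <- subjectParams(noise_sd = 0.4, n_frames = 30, seed = 77)
  d1 <- generateSubject(p)
  d2 <- generateSubject(p)
  expect_identical(d1$sequences$LV_endo_2ch@frames,
                   d2$sequences$LV_endo_2ch@frames)
  expect_identical(d1$echo, d2$echo)
  d3 <- generateSubject(subjectParams(noise_sd = 0.4, n_frames = 30,
                                      seed = 78))
  expect_false(identical(d1$sequences$LV_endo_2ch@frames,
                         d3$sequences$LV_endo_2ch@frames))
})

test_that("radial jitter has the configured magnitude and keeps contours simple", {
  p0 <- subjectParams(noise_sd = 0, n_frames = 30, seed = 12)
  p1 <- subjectParams(noise_sd = 0.5, n_frames = 30, seed = 12)
  clean <- generateSubject(p0, sax = FALSE)
  noisy <- generateSubject(p1, sax = FALSE)
  # per-point displacement is half-normal with mean sd*sqrt(2/pi)
  devs <- unlist(lapply(1:30, function(f) {
    d <- noisy$sequences$LA_endo_2ch@frames[[f]] -
      clean$sequences$LA_endo_2ch@frames[[f]]
    sqrt(rowSums(d^2))
  }))
  expect_equal(mean(devs), 0.5 * sqrt(2 / pi), tolerance = 0.05)
  for (f in c(1, 15, 30))
    expect_true(hyforce:::.isSimplePolygon(noisy$sequences$LA_endo_2ch@frames[[f]]))
  # excessive noise is refused, not clipped
  expect_error(generateSubject(subjectParams(noise_sd = 40, seed = 12)),
               "radius")
})

test_that("generateCohort draws the requested cohort with unique subjects", {
  cfg <- cohortConfig(n_subjects = 12, sax = FALSE, master_seed = 5,
                      n_frames_range = c(30L, 36L))
  cd <- generateCohort(cfg)
  expect_equal(nrow(cd$cohort), 12)
  expect_equal(anyDuplicated(cd$cohort$subject_id), 0L)
  expect_equal(nrow(cd$groundTruth), 12)
  expect_true(all(cd$cohort$age >= 20 & cd$cohort$age <= 81))
  expect_true(all(cd$cohort$n_frames >= 30 & cd$cohort$n_frames <= 36))
  # determinism of the whole cohort
  cd2 <- generateCohort(cfg)
  expect_identical(cd$cohort, cd2$cohort)
  expect_identical(cd$groundTruth, cd2$groundTruth)
})

test_that("configured age effects drive the ground-truth HyF, and null effects do not", {
  cfg <- cohortConfig(n_subjects = 40, sax = FALSE, master_seed = 3,
                      n_frames_range = c(30L, 40L))
  cd <- generateCohort(cfg)
  fit <- linregUnivariate(cd$cohort$age, cd$groundTruth$true_hyf)
  expect_lt(fit$slope, 0)
  expect_lt(fit$p_value, 0.001)
  # with the age effects switched off the slope is null
  cfg0 <- cohortConfig(n_subjects = 40, sax = FALSE, master_seed = 3,
                       age_effect_lv = 0, age_effect_la = 0,
                       age_effect_filling = 0, age_effect_reservoir = 0,
                       n_frames_range = c(30L, 40L))
  cd0 <- generateCohort(cfg0)
  fit0 <- linregUnivariate(cd0$cohort$age, cd0$groundTruth$true_hyf)
  expect_gt(fit0$p_value, 0.01)
})

test_that("echo record tracks the latent filling ratio", {
  cfg <- cohortConfig(n_subjects = 40, sax = FALSE, master_seed = 8,
                      echo_noise_sd = 1, n_frames_range = c(30L, 34L))
  cd <- generateCohort(cfg)
  ea <- cd$cohort$E / cd$cohort$A
  expect_gt(stats::cor(ea, cd$cohort$Eprime), 0.7)
  expect_lt(stats::cor(ea, cd$cohort$age), 0)    # E/A falls with age
})
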