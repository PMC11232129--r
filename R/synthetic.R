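# Synthetic cine-contour cohort generator. Emulates feature-tracking output
# for a healthy aging cohort: tri-phasic atrial and bi-phasic ventricular
# diastolic waveforms, age-dependent ventricular transverse shrinkage and
# atrial dilation, echo parameters tied to a latent diastolic-function
# variable, and contour-point measurement noise. Ground truth is recorded for
# every subject so the measurement pipeline can be validated against it.

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Subject-level generator parameters
#'
#' All geometry in mm. The left atrium is modeled as an ellipse and the left
#' ventricle as a half-ellipse truncated at the base and closed by the mitral
#' line; a single time-varying scale factor per chamber (the waveform) drives
#' the cycle. `filling_ratio` is the early-to-late inflow amplitude ratio (the
#' E/A analog) splitting diastolic filling between the early wave and the
#' atrial kick.
#'
#' @param subject_id identifier.
#' @param age years.
#' @param sex `"M"` or `"F"`.
#' @param height,weight cm and kg (BMI is derived, never supplied).
#' @param hr heart rate, bpm (sets the RR interval).
#' @param n_frames frames per cardiac cycle, 30-60 typical (>= 8 required).
#' @param lv_base_semiaxes,la_base_semiaxes `c(long, short)` semiaxes in mm.
#' @param filling_ratio early/late filling amplitude ratio (> 0).
#' @param diastasis_fraction fraction of diastole occupied by the plateau,
#'   in (0, 1).
#' @param lv_contraction peak fractional shortening of the LV scale (0.17
#'   gives GLS of -17 percent).
#' @param la_reservoir peak fractional expansion of the LA scale (0.30 gives
#'   reservoir strain of 30 percent).
#' @param wall_thickness end-diastolic LV wall thickness, mm.
#' @param thickening_coef systolic wall-thickening gain: the wall thickness is
#'   `wall_thickness * (1 + thickening_coef * (1 - s(t)))`.
#' @param systole_fraction fraction of the cycle occupied by systole.
#' @param noise_sd contour-point radial jitter SD, mm.
#' @param echo_noise_sd echo velocity noise SD, cm/s.
#' @param n_points points per long-axis contour (>= 48).
#' @param sax_points points per short-axis contour.
#' @param n_slices,slice_thickness short-axis stack geometry (mm, no gap).
#' @param seed integer RNG seed; fixes the subject byte-for-byte.
#' @return a validated list of class `SubjectParams`.
#' @export
subjectParams <- function(subject_id = "S001", age = 45, sex = c("M", "F"),
                          height = 175, weight = 72, hr = 68, n_frames = 40L,
                          lv_base_semiaxes = c(66, 21),
                          la_base_semiaxes = c(28, 14),
                          filling_ratio = 1.3, diastasis_fraction = 0.30,
                          lv_contraction = 0.17, la_reservoir = 0.30,
                          wall_thickness = 8, thickening_coef = 3.3,
                          systole_fraction = 0.35,
                          noise_sd = 0, echo_noise_sd = 4,
                          n_points = 96L, sax_points = 64L,
                          n_slices = 10L, slice_thickness = 8,
                          seed = 1L) {
  sex <- match.arg(sex)
  n_frames <- as.integer(n_frames)
  if (n_frames < 8L) stop("n_frames too small to represent the four cardiac phases (< 8)")
  if (diastasis_fraction <= 0 || diastasis_fraction >= 1)
    stop("diastasis_fraction must lie strictly in (0, 1)")
  if (any(c(lv_base_semiaxes, la_base_semiaxes) <= 0)) stop("semiaxes must be positive")
  if (filling_ratio <= 0) stop("filling_ratio must be positive")
  if (lv_contraction <= 0 || lv_contraction >= 1) stop("lv_contraction in (0,1)")
  if (la_reservoir <= 0) stop("la_reservoir must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (n_points < 48L) stop("at least 48 points per long-axis contour")
  p <- list(subject_id = as.character(subject_id), age = age, sex = sex,
            height = height, weight = weight,
            bmi = weight / (height / 100)^2, hr = hr, n_frames = n_frames,
            lv_base_semiaxes = as.numeric(lv_base_semiaxes),
            la_base_semiaxes = as.numeric(la_base_semiaxes),
            filling_ratio = filling_ratio,
            diastasis_fraction = diastasis_fraction,
            lv_contraction = lv_contraction, la_reservoir = la_reservoir,
            wall_thickness = wall_thickness, thickening_coef = thickening_coef,
            systole_fraction = systole_fraction,
            noise_sd = noise_sd, echo_noise_sd = echo_noise_sd,
            n_points = as.integer(n_points), sax_points = as.integer(sax_points),
            n_slices = as.integer(n_slices), slice_thickness = slice_thickness,
            seed = as.integer(seed))
  class(p) <- "SubjectParams"
  p
}

.ease <- function(x) (1 - cos(pi * .clamp(x, 0, 1))) / 2

.phaseBoundaries <- function(params) {
  sys <- params$systole_fraction
  D <- 1 - sys
  pl <- params$diastasis_fraction * D
  e <- 0.6 * (D - pl)
  k <- 0.4 * (D - pl)
  list(t1 = sys, t2 = sys + e, t3 = sys + e + pl, e_len = e, k_len = k,
       p_len = pl)
}

#' Per-frame chamber scale-factor waveform
#'
#' Piecewise-cosine segments joined continuously at the phase boundaries:
#' systole, early filling wave, diastasis plateau (exactly constant), atrial
#' kick back to the end-diastolic value. Frame 1 (end-diastole) is the
#' reference scale 1.0; the curve is periodic (first value equals last). The
#' LV scale is maximal at frame 1 and minimal at end-systole; the LA scale is
#' minimal at frame 1 and maximal at ventricular end-systole, with a two-step
#' descent (conduit, then booster) split by `filling_ratio`.
#'
#' @param role `"LV"` or `"LA"`.
#' @param params a [subjectParams()] list.
#' @return numeric scale factor per frame.
#' @export
chamberWaveform <- function(role = c("LV", "LA"), params) {
  role <- match.arg(role)
  n <- params$n_frames
  if (n < 8L) stop("n_frames too small to represent the four cardiac phases (< 8)")
  if (params$diastasis_fraction <= 0 || params$diastasis_fraction >= 1)
    stop("diastasis_fraction must lie strictly in (0, 1)")
  u <- (seq_len(n) - 1) / (n - 1)
  b <- .phaseBoundaries(params)
  r <- params$filling_ratio
  out <- numeric(n)
  if (role == "LV") {
    cc <- params$lv_contraction
    earlyAmp <- cc * r / (1 + r)
    sMin <- 1 - cc
    sPl <- sMin + earlyAmp
    out <- ifelse(u <= b$t1, 1 - cc * .ease(u / b$t1),
           ifelse(u <= b$t2, sMin + earlyAmp * .ease((u - b$t1) / b$e_len),
           ifelse(u <= b$t3, sPl,
                  sPl + (1 - sPl) * .ease((u - b$t3) / b$k_len))))
  } else {
    R <- params$la_reservoir
    conduit <- R * r / (1 + r)
    booster <- R / (1 + r)
    out <- ifelse(u <= b$t1, 1 + R * .ease(u / b$t1),
           ifelse(u <= b$t2, (1 + R) - conduit * .ease((u - b$t1) / b$e_len),
           ifelse(u <= b$t3, 1 + booster,
                  (1 + booster) - booster * .ease((u - b$t3) / b$k_len))))
  }
  out
}

#' Phase landmarks of the programmed waveform
#'
#' @param params a [subjectParams()] list.
#' @return list with `plateau_frames` (first/last frame of the diastasis
#'   plateau, 1-based), `es_frame` (grid frame nearest end-systole) and the
#'   normalized phase boundaries `t1`, `t2`, `t3`.
#' @export
waveformPhases <- function(params) {
  n <- params$n_frames
  u <- (seq_len(n) - 1) / (n - 1)
  b <- .phaseBoundaries(params)
  onPlateau <- which(u >= b$t2 - 1e-12 & u <= b$t3 + 1e-12)
  if (!length(onPlateau)) onPlateau <- which.min(abs(u - (b$t2 + b$t3) / 2))
  list(plateau_frames = c(min(onPlateau), max(onPlateau)),
       es_frame = which.min(abs(u - b$t1)),
       t1 = b$t1, t2 = b$t2, t3 = b$t3)
}

# Radial jitter about a center; preserves angular order, hence simplicity.
.jitterRadial <- function(pts, center, sd) {
  if (sd <= 0) return(pts)
  rel <- sweep(pts, 2, center)
  rr <- sqrt(rowSums(rel^2))
  if (any(rr < 1e-9)) stop("contour point coincides with jitter center")
  eps <- stats::rnorm(nrow(pts), 0, sd)
  newr <- rr + eps
  if (any(newr <= 0.05))
    stop("contour jitter produced a non-positive radius; noise_sd too large for the geometry")
  sweep(rel * (newr / rr), 2, center, `+`)
}

.lvLongAxisPoints <- function(aa, bb, npts, baseY = 0) {
  phi <- pi * (seq_len(npts) - 1) / (npts - 1)
  cbind(bb * cos(phi), baseY + aa * sin(phi))
}

.laPoints <- function(aa, bb, npts, centerY) {
  phi <- 2 * pi * (seq_len(npts) - 1) / npts
  cbind(bb * cos(phi), centerY + aa * sin(phi))
}

.circlePoints <- function(r, npts) {
  phi <- 2 * pi * (seq_len(npts) - 1) / npts
  cbind(r * cos(phi), r * sin(phi))
}

#' Generate one synthetic subject
#'
#' Emits tracked contour sequences (LV endo/epi and LA endo in the 2- and
#' 4-chamber views, plus an optional short-axis stack), an echo record tied to
#' the subject's filling ratio, and the analytic ground truth (area curves,
#' diastasis window, hydraulic force, strains, volumes). With `noise_sd = 0`
#' the LA contour at every frame is an exact ellipse with semiaxes scaled by
#' the waveform. Deterministic for a fixed seed.
#'
#' @param params a [subjectParams()] list.
#' @param sax generate the short-axis stack (default TRUE).
#' @return a list of class `SubjectDataset` with elements `params`,
#'   `sequences` (named list of [ContourSequence-class]; short-axis stacks
#'   under `sax_endo` and `sax_epi`), `echo` and `groundTruth`.
#' @export
generateSubject <- function(params, sax = TRUE) {
  stopifnot(inherits(params, "SubjectParams"))
  set.seed(params$seed)
  n <- params$n_frames
  sLV <- chamberWaveform("LV", params)
  sLA <- chamberWaveform("LA", params)
  aLV <- params$lv_base_semiaxes[1]; bLV <- params$lv_base_semiaxes[2]
  aLA <- params$la_base_semiaxes[1]; bLA <- params$la_base_semiaxes[2]
  th0 <- params$wall_thickness
  th <- th0 * (1 + params$thickening_coef * (1 - sLV))
  laGap <- 8
  laCenterY <- -(laGap + aLA * max(sLA))
  rr <- 60000 / params$hr
  sd <- params$noise_sd

  mkSeq <- function(view, chamber, frames, closed,
                    sliceLocation = NA_real_, sliceThickness = NA_real_) {
    ContourSequence(params$subject_id, view, chamber, frames, closed = closed,
                    rrInterval = rr, sliceLocation = sliceLocation,
                    sliceThickness = sliceThickness)
  }

  # Apex fixed at y = aLV, the base plane descends towards it in systole
  # (atrioventricular-plane descent); the LA keeps a fixed center above the
  # end-diastolic base plane.
  baseY <- aLV * (1 - sLV)
  longAxisView <- function(view) {
    lvEndo <- lapply(seq_len(n), function(f)
      .jitterRadial(.lvLongAxisPoints(aLV * sLV[f], bLV * sLV[f],
                                      params$n_points, baseY[f]),
                    c(0, baseY[f] + 0.3 * aLV * sLV[f]), sd))
    lvEpi <- lapply(seq_len(n), function(f)
      .jitterRadial(.lvLongAxisPoints(aLV * sLV[f] + th[f],
                                      bLV * sLV[f] + th[f],
                                      params$n_points, baseY[f]),
                    c(0, baseY[f] + 0.3 * (aLV * sLV[f] + th[f])), sd))
    laEndo <- lapply(seq_len(n), function(f)
      .jitterRadial(.laPoints(aLA * sLA[f], bLA * sLA[f], params$n_points,
                              laCenterY), c(0, laCenterY), sd))
    list(mkSeq(view, "LV_endo", lvEndo, closed = FALSE),
         mkSeq(view, "LV_epi", lvEpi, closed = FALSE),
         mkSeq(view, "LA_endo", laEndo, closed = TRUE))
  }

  v2 <- longAxisView("2ch")
  v4 <- longAxisView("4ch")
  sequences <- list(LV_endo_2ch = v2[[1]], LV_epi_2ch = v2[[2]],
                    LA_endo_2ch = v2[[3]], LV_endo_4ch = v4[[1]],
                    LV_epi_4ch = v4[[2]], LA_endo_4ch = v4[[3]])

  # Cavity radius at a fixed slice position z (distance from the
  # end-diastolic base plane); h is measured from the moving base plane.
  rEndoAt <- function(z, f) {
    ax <- aLV * sLV[f]
    h <- z - baseY[f]
    if (h < 0 || h > ax) return(0.05)
    max(bLV * sLV[f] * sqrt(max(0, 1 - (h / ax)^2)), 0.05)
  }
  rEpiAt <- function(z, f) {
    ax <- aLV * sLV[f] + th[f]
    h <- z - baseY[f]
    if (h < 0 || h > ax) return(rEndoAt(z, f) + 0.05)
    max((bLV * sLV[f] + th[f]) * sqrt(max(0, 1 - (h / ax)^2)),
        rEndoAt(z, f) + 0.05)
  }
  if (sax) {
    zc <- (seq_len(params$n_slices) - 0.5) * params$slice_thickness
    saxEndo <- lapply(zc, function(z) {
      frames <- lapply(seq_len(n), function(f)
        .jitterRadial(.circlePoints(rEndoAt(z, f), params$sax_points),
                      c(0, 0), if (rEndoAt(z, f) > 1) sd else 0))
      mkSeq("sax", "LV_endo", frames, closed = TRUE, sliceLocation = z,
            sliceThickness = params$slice_thickness)
    })
    saxEpi <- lapply(zc, function(z) {
      frames <- lapply(seq_len(n), function(f)
        .jitterRadial(.circlePoints(rEpiAt(z, f), params$sax_points),
                      c(0, 0), if (rEpiAt(z, f) > 1) sd else 0))
      mkSeq("sax", "LV_epi", frames, closed = TRUE, sliceLocation = z,
            sliceThickness = params$slice_thickness)
    })
    sequences$sax_endo <- saxEndo
    sequences$sax_epi <- saxEpi
  }

  # echo record: velocities anchored to the latent diastolic-function variable
  r <- params$filling_ratio
  esd <- params$echo_noise_sd
  Avel <- max(20, 55 + 0.55 * (params$age - 32.5) + stats::rnorm(1, 0, esd))
  Evel <- max(20, r * Avel + stats::rnorm(1, 0, esd / 2))
  Eprime <- max(3, 3.5 + 9 * r + stats::rnorm(1, 0, esd / 4))
  echo <- list(E = Evel, A = Avel, Eprime = Eprime)

  # analytic ground truth on the emitted (noise-free) frame grid
  ph <- waveformPhases(params)
  trueLvArea <- pi * (bLV * sLV)^2 / 100
  trueLaArea <- pi * (bLA * sLA)^2 / 100
  win <- ph$plateau_frames
  trueHyf <- mean(trueLvArea[win[1]:win[2]] - trueLaArea[win[1]:win[2]])

  mid <- .midThird(params$n_slices)
  zcAll <- (seq_len(params$n_slices) - 0.5) * params$slice_thickness
  gcsCurves <- vapply(seq_len(n), function(f) {
    mean(vapply(zcAll[mid], function(z)
      100 * (rEndoAt(z, f) / rEndoAt(z, 1) - 1), numeric(1)))
  }, numeric(1))
  thickCurve <- vapply(seq_len(n), function(f) {
    mean(vapply(zcAll[mid], function(z) rEpiAt(z, f) - rEndoAt(z, f),
                numeric(1)))
  }, numeric(1))
  laStrain <- 100 * (sLA - 1)
  tMax <- which.max(laStrain)
  tPreA <- win[2]
  trueStrains <- c(
    lv_gls = 100 * (min(sLV) - 1),
    lv_gcs = min(gcsCurves),
    lv_grs = max(100 * (thickCurve - thickCurve[1]) / thickCurve[1]),
    la_slr = laStrain[tMax],
    la_slc = laStrain[tMax] - laStrain[tPreA],
    la_slb = laStrain[tPreA] - laStrain[n])

  halfEllipsoid <- function(aa, bb) (2 / 3) * pi * aa * bb^2 / 1000
  fullEllipsoid <- function(aa, bb) (4 / 3) * pi * aa * bb^2 / 1000
  lvVol <- halfEllipsoid(aLV, bLV) * sLV^3
  laVol <- fullEllipsoid(aLA, bLA) * sLA^3
  epiEdv <- halfEllipsoid(aLV + th0, bLV + th0)
  trueVolumes <- c(lv_edv = max(lvVol), lv_esv = min(lvVol),
                   la_edv = max(laVol), la_esv = min(laVol),
                   lv_mass = 1.05 * (epiEdv - halfEllipsoid(aLV, bLV)))

  gt <- list(true_lv_area_curve = trueLvArea, true_la_area_curve = trueLaArea,
             true_diastasis_window = win, true_hyf = trueHyf,
             true_strains = trueStrains, true_volumes = trueVolumes,
             lv_scale = sLV, la_scale = sLA, t_max = tMax, t_preA = tPreA)

  structure(list(params = params, sequences = sequences, echo = echo,
                 groundTruth = gt), class = "SubjectDataset")
}

#' Cohort-level generator configuration
#'
#' Age effects are linear in decades about age 50 on the base geometry; the
#' latent diastolic-function variable (`filling_ratio`) and the atrial
#' reservoir amplitude decline with age, driving the echo record and the
#' atrial strain structure. The within-cohort correlation between LV and LA
#' size beyond the shared age trend is left at zero (independent residuals).
#'
#' @param n_subjects number of subjects (>= 2).
#' @param age_range `c(min, max)` years, within 18-90; ages drawn uniformly.
#' @param age_effect_lv change in the LV transverse semiaxis, mm/decade
#'   (negative: ventricular shrinkage).
#' @param age_effect_la change in the LA transverse semiaxis, mm/decade
#'   (positive: atrial dilation).
#' @param age_effect_filling per-decade decrease of the filling ratio.
#' @param age_effect_reservoir per-decade decrease of the LA reservoir
#'   amplitude (fraction, e.g. 0.021 per decade).
#' @param echo_noise_sd echo velocity noise SD, cm/s.
#' @param contour_noise_sd contour-point jitter SD, mm.
#' @param semiaxis_sd between-subject SD of the transverse semiaxes, mm.
#' @param lv_base_semiaxes,la_base_semiaxes base `c(long, short)` semiaxes at
#'   age 50, mm.
#' @param n_frames_range frames per cycle drawn uniformly from this range.
#' @param sax generate short-axis stacks.
#' @param master_seed integer seed; per-subject seeds are derived from it
#'   deterministically and recorded in the cohort table.
#' @return a validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(n_subjects = 119L, age_range = c(20, 81),
                         age_effect_lv = -0.8, age_effect_la = 0.9,
                         age_effect_filling = 0.18,
                         age_effect_reservoir = 0.021,
                         echo_noise_sd = 4, contour_noise_sd = 0.25,
                         semiaxis_sd = 1.2,
                         lv_base_semiaxes = c(66, 21),
                         la_base_semiaxes = c(28, 14),
                         n_frames_range = c(30L, 60L), sax = TRUE,
                         master_seed = 1L) {
  if (n_subjects < 2L) stop("n_subjects must be at least 2")
  if (age_range[1] < 18 || age_range[2] > 90 || age_range[1] > age_range[2])
    stop("age_range must lie within [18, 90]")
  cfg <- list(n_subjects = as.integer(n_subjects), age_range = age_range,
              age_effect_lv = age_effect_lv, age_effect_la = age_effect_la,
              age_effect_filling = age_effect_filling,
              age_effect_reservoir = age_effect_reservoir,
              echo_noise_sd = echo_noise_sd,
              contour_noise_sd = contour_noise_sd,
              semiaxis_sd = semiaxis_sd,
              lv_base_semiaxes = lv_base_semiaxes,
              la_base_semiaxes = la_base_semiaxes,
              n_frames_range = as.integer(n_frames_range), sax = isTRUE(sax),
              master_seed = as.integer(master_seed))
  class(cfg) <- "CohortConfig"
  cfg
}

.subjectSeed <- function(master_seed, idx) {
  as.integer(((as.numeric(master_seed) %% 1000003) * 7919 +
                as.numeric(idx) * 104729) %% 2147483629 + 1)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject demographics and geometry with the configured age
#' effects, generates each subject with [generateSubject()] under a seed
#' derived deterministically from `master_seed`, and assembles the cohort
#' table (demographics, blood pressures, echo record, per-subject seed) and
#' the ground-truth table.
#'
#' @param config a [cohortConfig()] list.
#' @return a list of class `CohortDataset`: `subjects` (list of
#'   `SubjectDataset`), `cohort` (data.frame, one row per subject),
#'   `groundTruth` (data.frame of true values), `config`.
#' @export
generateCohort <- function(config = cohortConfig()) {
  stopifnot(inherits(config, "CohortConfig"))
  nS <- config$n_subjects
  subjects <- vector("list", nS)
  cohortRows <- vector("list", nS)
  gtRows <- vector("list", nS)
  for (i in seq_len(nS)) {
    covSeed <- .subjectSeed(config$master_seed, i)
    subSeed <- .subjectSeed(config$master_seed, i + 5000000L)
    set.seed(covSeed)
    age <- stats::runif(1, config$age_range[1], config$age_range[2])
    sex <- if (stats::runif(1) < 0.5) "F" else "M"
    height <- if (sex == "M") stats::rnorm(1, 176, 6.5) else stats::rnorm(1, 163, 6)
    height <- .clamp(height, 145, 200)
    bmiDraw <- .clamp(stats::rnorm(1, if (sex == "M") 23.5 else 22.5, 2.8), 17, 35)
    weight <- bmiDraw * (height / 100)^2
    hr <- .clamp(stats::rnorm(1, 69, 9), 45, 100)
    nfChoices <- seq.int(config$n_frames_range[1], config$n_frames_range[2])
    nf <- nfChoices[sample.int(length(nfChoices), 1)]
    dec <- (age - 50) / 10
    sexF <- if (sex == "F") 0.92 else 1.0
    bLv <- .clamp(config$lv_base_semiaxes[2] + config$age_effect_lv * dec +
                    stats::rnorm(1, 0, config$semiaxis_sd), 12, 32)
    aLv <- .clamp(config$lv_base_semiaxes[1] + stats::rnorm(1, 0, 2.5), 58, 71.9)
    bLa <- .clamp(config$la_base_semiaxes[2] + config$age_effect_la * dec +
                    stats::rnorm(1, 0, config$semiaxis_sd), 8, 26)
    aLa <- .clamp(config$la_base_semiaxes[1] + stats::rnorm(1, 0, 2), 20, 36)
    fillingRatio <- .clamp(1.2 - config$age_effect_filling * dec +
                             stats::rnorm(1, 0, 0.12), 0.45, 3)
    diastasisFraction <- .clamp(stats::rnorm(1, 0.30, 0.04), 0.15, 0.45)
    lvContraction <- .clamp(stats::rnorm(1, 0.17, 0.015), 0.12, 0.22)
    laReservoir <- .clamp(0.285 - config$age_effect_reservoir * dec +
                            stats::rnorm(1, 0, 0.025), 0.15, 0.45)
    sbp <- .clamp(105 + 2.2 * dec + 7 + stats::rnorm(1, 0, 8), 85, 175)
    dbp <- .clamp(66 + 1.2 * dec + 3 + stats::rnorm(1, 0, 6), 45, 110)
    params <- subjectParams(
      subject_id = sprintf("S%03d", i), age = age, sex = sex,
      height = height, weight = weight, hr = hr, n_frames = nf,
      lv_base_semiaxes = c(aLv, bLv) * sexF,
      la_base_semiaxes = c(aLa, bLa) * sexF,
      filling_ratio = fillingRatio, diastasis_fraction = diastasisFraction,
      lv_contraction = lvContraction, la_reservoir = laReservoir,
      noise_sd = config$contour_noise_sd,
      echo_noise_sd = config$echo_noise_sd, seed = subSeed)
    ds <- tryCatch(generateSubject(params, sax = config$sax),
                   error = function(e)
                     stop(sprintf("subject %s: %s", params$subject_id,
                                  conditionMessage(e)), call. = FALSE))
    subjects[[i]] <- ds
    cohortRows[[i]] <- data.frame(
      subject_id = params$subject_id, age = age, sex = sex, height = height,
      weight = weight, bmi = params$bmi, sbp = sbp, dbp = dbp, hr = hr,
      E = ds$echo$E, A = ds$echo$A, Eprime = ds$echo$Eprime,
      n_frames = nf, seed = subSeed, stringsAsFactors = FALSE)
    gt <- ds$groundTruth
    gtRows[[i]] <- data.frame(
      subject_id = params$subject_id, true_hyf = gt$true_hyf,
      true_lv_area_diastasis = mean(
        gt$true_lv_area_curve[gt$true_diastasis_window[1]:gt$true_diastasis_window[2]]),
      true_la_area_diastasis = mean(
        gt$true_la_area_curve[gt$true_diastasis_window[1]:gt$true_diastasis_window[2]]),
      t(gt$true_strains), t(gt$true_volumes), stringsAsFactors = FALSE)
  }
  cohort <- do.call(rbind, cohortRows)
  if (anyDuplicated(cohort$subject_id)) stop("duplicate subject_id generated")
  structure(list(subjects = subjects, cohort = cohort,
                 groundTruth = do.call(rbind, gtRows), config = config),
            class = "CohortDataset")
}
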