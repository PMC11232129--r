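# Pipeline orchestration: per-subject analysis, cohort runs with QC-based
# exclusions and statistics, and operator-reproducibility simulation.

#' Pipeline configuration
#'
#' All defaults are materialized here and echoed into every output so a result
#' is traceable to its configuration.
#'
#' @param area_mode diameter-to-area rule, `"biplane_ellipse"` or
#'   `"single_plane"`.
#' @param diastasis_theta relative rate threshold of the diastasis detector.
#' @param station_step station spacing of the diameter scan, mm.
#' @param bsa_formula `"dubois"` or `"mosteller"`.
#' @param icc_model ICC model label (informational; ICC(2,1) is computed).
#' @param seed integer seed for any stochastic step (reproducibility jitter).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(area_mode = c("biplane_ellipse", "single_plane"),
                           diastasis_theta = 0.2, station_step = 0.25,
                           bsa_formula = c("dubois", "mosteller"),
                           icc_model = "two-way random, absolute agreement, single measure",
                           seed = 1L) {
  structure(list(area_mode = match.arg(area_mode),
                 diastasis_theta = diastasis_theta,
                 station_step = station_step,
                 bsa_formula = match.arg(bsa_formula),
                 icc_model = icc_model, seed = as.integer(seed)),
            class = "PipelineConfig")
}

# Group a flat list of ContourSequence into the named layout used by
# analyzeSubject: long-axis sequences keyed <chamber>_<view>, short-axis
# stacks ordered base to apex under sax_endo / sax_epi.
.organizeSequences <- function(seqs) {
  out <- list()
  saxEndo <- list(); saxEpi <- list()
  for (s in seqs) {
    if (s@view == "sax") {
      if (s@chamber == "LV_endo") saxEndo[[length(saxEndo) + 1L]] <- s
      else if (s@chamber == "LV_epi") saxEpi[[length(saxEpi) + 1L]] <- s
    } else {
      out[[paste(s@chamber, s@view, sep = "_")]] <- s
    }
  }
  if (length(saxEndo))
    out$sax_endo <- saxEndo[order(vapply(saxEndo, function(s) s@sliceLocation,
                                         numeric(1)))]
  if (length(saxEpi))
    out$sax_epi <- saxEpi[order(vapply(saxEpi, function(s) s@sliceLocation,
                                       numeric(1)))]
  out
}

#' Analyze one subject's contour sequences
#'
#' Runs the full per-subject measurement chain: per-frame area curves with the
#' long axis recomputed each frame, hydraulic-force analysis with diastasis
#' detection, LV global strains, LA tri-phasic strain (the
#' pre-atrial-contraction frame is the last frame of the detected diastasis
#' window), Simpson LV volumes and mass when a short-axis stack is present,
#' biplane area-length LA volumes, ejection fractions and BSA indexing when
#' anthropometrics are supplied. Missing inputs leave the corresponding fields
#' `NA` with a QC flag; they are never silently defaulted.
#'
#' @param sequences either a flat list of [ContourSequence-class] objects, a
#'   named list with entries `LV_endo_2ch`, `LA_endo_2ch`, `LV_endo_4ch`,
#'   `LA_endo_4ch` (plus optional `LV_epi_*`, `sax_endo`, `sax_epi`), or a
#'   `SubjectDataset`.
#' @param covariates optional one-row data.frame or list with `height` (cm)
#'   and `weight` (kg) for BSA indexing.
#' @param config a [pipelineConfig()].
#' @return one-row data.frame of derived indices; attributes `curves` (the
#'   per-frame LV/LA area and difference curves) and `config`.
#' @export
analyzeSubject <- function(sequences, covariates = NULL,
                           config = pipelineConfig()) {
  if (inherits(sequences, "SubjectDataset")) sequences <- sequences$sequences
  if (is.null(names(sequences)) ||
      !all(c("LV_endo_2ch", "LA_endo_2ch") %in% names(sequences)))
    sequences <- .organizeSequences(sequences)
  need <- c("LV_endo_2ch", "LA_endo_2ch", "LV_endo_4ch", "LA_endo_4ch")
  if (!all(need %in% names(sequences)))
    stop(sprintf("missing mandatory sequences: %s",
                 paste(setdiff(need, names(sequences)), collapse = ", ")))
  qc <- character()

  ac <- areaCurves(lv2ch = sequences$LV_endo_2ch, la2ch = sequences$LA_endo_2ch,
                   lv4ch = sequences$LV_endo_4ch, la4ch = sequences$LA_endo_4ch,
                   mode = config$area_mode, step = config$station_step)
  n <- nFrames(ac$LV)
  hy <- hyfAnalysis(ac$LV, ac$LA, theta = config$diastasis_theta)
  qc <- c(qc, qcFlags(hy))
  win <- diastasisWindow(hy)
  lvFD <- ac$LV@frameData; laFD <- ac$LA@frameData

  gls <- suppressWarnings(lvGls(lvFD$len_2ch, lvFD$len_4ch))
  laCurve2 <- strainCurve(laFD$len_2ch)
  laCurve4 <- strainCurve(laFD$len_4ch)
  laStrain <- (laCurve2 + laCurve4) / 2
  tMax <- which.max(laStrain)
  tPreA <- win[2]
  laPh <- c(la_slr = NA_real_, la_slc = NA_real_, la_slb = NA_real_,
            la_residual = NA_real_)
  if (tMax > 1 && tPreA > tMax && tPreA < n) {
    laPh <- laPhasicStrain(laStrain, tMax, tPreA)
  } else {
    qc <- c(qc, "la_phase_order")
  }

  gcs <- grs <- lvEdv <- lvEsv <- lvEf <- lvMassVal <- NA_real_
  haveSax <- !is.null(sequences$sax_endo)
  if (haveSax) {
    saxEndo <- sequences$sax_endo
    nf <- nFrames(saxEndo[[1]])
    if (nf != n) stop("short-axis frame count differs from long-axis views")
    endoAreas <- vapply(saxEndo, function(s)
      vapply(s@frames, polygonArea, numeric(1), check = FALSE), numeric(nf))
    endoAreas <- t(endoAreas) # slices x frames
    thick <- saxEndo[[1]]@sliceThickness
    lvVol <- lvVolumeSimpson(endoAreas, thickness = thick)
    lvEdv <- max(lvVol); lvEsv <- min(lvVol)
    lvEf <- ejectionFraction(lvEdv, lvEsv)
    perims <- t(vapply(saxEndo, function(s)
      vapply(s@frames, contourLength, numeric(1), closed = TRUE), numeric(nf)))
    gcs <- lvGcs(perims)
    if (!is.null(sequences$sax_epi)) {
      saxEpi <- sequences$sax_epi
      epiAreas <- t(vapply(saxEpi, function(s)
        vapply(s@frames, polygonArea, numeric(1), check = FALSE), numeric(nf)))
      epiVol <- lvVolumeSimpson(epiAreas, thickness = thick)
      edFrame <- which.max(lvVol)
      lvMassVal <- lvMass(epiVol[edFrame], lvVol[edFrame])
      grs <- lvGrs(saxEndo, saxEpi)
    } else {
      qc <- c(qc, "no_sax_epi")
    }
  } else {
    qc <- c(qc, "no_sax")
  }

  laVol <- laVolumeBiplane(laFD$polyarea_2ch, laFD$polyarea_4ch,
                           laFD$axlen_2ch, laFD$axlen_4ch)
  laEdv <- max(laVol); laEsv <- min(laVol)
  laEf <- ejectionFraction(laEdv, laEsv)

  bsa <- NA_real_
  if (!is.null(covariates) && !is.null(covariates$height) &&
      !is.null(covariates$weight) && is.finite(covariates$height) &&
      is.finite(covariates$weight)) {
    bsa <- bodySurfaceArea(covariates$height, covariates$weight,
                           formula = config$bsa_formula)
  } else {
    qc <- c(qc, "no_anthropometrics")
  }
  idx <- function(v) if (is.finite(bsa)) v / bsa else NA_real_

  rec <- data.frame(
    subject_id = sequences$LV_endo_2ch@subjectId,
    n_frames = n,
    hyf = hyf(hy),
    dia_start = win[1], dia_end = win[2],
    e_peak_frame = hy@ePeakFrame, a_peak_frame = hy@aPeakFrame,
    lv_area_diastasis = mean(areas(ac$LV)[win[1]:win[2]]),
    la_area_diastasis = mean(areas(ac$LA)[win[1]:win[2]]),
    lv_gls = gls, lv_gcs = gcs, lv_grs = grs,
    la_slr = unname(laPh["la_slr"]), la_slc = unname(laPh["la_slc"]),
    la_slb = unname(laPh["la_slb"]),
    la_residual = unname(laPh["la_residual"]),
    t_max = tMax, t_preA = tPreA,
    lv_edv = lvEdv, lv_esv = lvEsv, lv_ef = lvEf, lv_mass = lvMassVal,
    la_edv = laEdv, la_esv = laEsv, la_ef = laEf,
    bsa = bsa,
    lv_edvi = idx(lvEdv), lv_esvi = idx(lvEsv), lv_massi = idx(lvMassVal),
    la_edvi = idx(laEdv), la_esvi = idx(laEsv),
    qc_flags = paste(unique(qc), collapse = ";"),
    stringsAsFactors = FALSE)
  attr(rec, "curves") <- list(times = frameTimes(ac$LV),
                              lv_area = areas(ac$LV), la_area = areas(ac$LA),
                              diff = hy@diffCurve)
  attr(rec, "config") <- config
  rec
}

#' Analyze a subject from a contour file
#'
#' @param contours path to a contour-sequence JSON file, or any input accepted
#'   by [analyzeSubject()].
#' @param config a [pipelineConfig()].
#' @param covariates optional anthropometrics, see [analyzeSubject()].
#' @return see [analyzeSubject()].
#' @export
runSubject <- function(contours, config = pipelineConfig(),
                       covariates = NULL) {
  if (is.character(contours) && length(contours) == 1L)
    contours <- readContourFile(contours)
  analyzeSubject(contours, covariates = covariates, config = config)
}

.loadCohortInput <- function(input) {
  if (inherits(input, "CohortDataset")) {
    return(list(cohort = input$cohort,
                getSequences = function(id) {
                  i <- match(id, vapply(input$subjects,
                                        function(s) s$params$subject_id, ""))
                  input$subjects[[i]]$sequences
                }))
  }
  if (is.character(input) && dir.exists(input)) {
    cohort <- readCohortCsv(file.path(input, "cohort.csv"))
    return(list(cohort = cohort,
                getSequences = function(id)
                  readContourFile(file.path(input,
                                            sprintf("contours_%s.json", id)))))
  }
  stop("input must be a CohortDataset or a cohort directory")
}

#' Run the full cohort analysis
#'
#' Analyzes every subject, excludes those failing hard QC (unparseable
#' contours, no diastolic limb) while recording them in an exclusion report,
#' merges the derived indices with the cohort covariates (recomputing E/A and
#' E/E'), and computes the cohort statistics.
#'
#' @param input a `CohortDataset` from [generateCohort()] or a directory
#'   written by [writeCohortDataset()].
#' @param config a [pipelineConfig()].
#' @return list of class `hyf_cohort_run`: `results` (analyzed table),
#'   `report` (see [buildReport()]), `exclusions` (data.frame), `curves`
#'   (per-subject area-curve list), `config`.
#' @export
runCohort <- function(input, config = pipelineConfig()) {
  src <- .loadCohortInput(input)
  cohort <- src$cohort
  cohort$n_frames <- NULL # re-reported per analyzed subject
  if (!"E_A" %in% names(cohort) && all(c("E", "A") %in% names(cohort))) {
    cohort$E_A <- cohort$E / cohort$A
    cohort$E_Ep <- cohort$E / cohort$Eprime
  }
  recs <- list(); excl <- list(); curves <- list()
  for (i in seq_len(nrow(cohort))) {
    id <- cohort$subject_id[i]
    rec <- tryCatch(
      analyzeSubject(src$getSequences(id), covariates = cohort[i, ],
                     config = config),
      error = function(e) e)
    if (inherits(rec, "error")) {
      excl[[length(excl) + 1L]] <- data.frame(
        subject_id = id, reason = conditionMessage(rec),
        stringsAsFactors = FALSE)
    } else {
      curves[[id]] <- attr(rec, "curves")
      recs[[length(recs) + 1L]] <- rec
    }
  }
  if (!length(recs)) stop("empty cohort after exclusions")
  results <- merge(cohort, do.call(rbind, recs), by = "subject_id",
                   sort = TRUE)
  report <- buildReport(results)
  structure(list(results = results, report = report,
                 exclusions = if (length(excl)) do.call(rbind, excl)
                              else data.frame(subject_id = character(),
                                              reason = character()),
                 curves = curves, config = config),
            class = "hyf_cohort_run")
}

.jitterSequence <- function(s, sd) {
  if (sd <= 0) return(s)
  frames <- lapply(s@frames, function(p)
    .jitterRadial(p, polygonCentroid(p, check = FALSE), sd))
  ContourSequence(s@subjectId, s@view, s@chamber, frames, closed = s@closed,
                  rrInterval = s@rrInterval, sliceLocation = s@sliceLocation,
                  sliceThickness = s@sliceThickness)
}

#' Operator-reproducibility simulation for the hydraulic force
#'
#' Emulates repeated contouring: for each selected subject the hydraulic
#' force is re-measured after independently perturbing the long-axis contours
#' with radial jitter (one extra perturbation set per "operator" pass), and
#' the intra-operator (pass 1 vs pass 2 of operator 1) and inter-operator
#' (operator 1 vs operator 2) ICCs of HyF are computed.
#'
#' @param input a `CohortDataset` or cohort directory.
#' @param n number of subjects to sample (default 20).
#' @param jitterSd contour jitter SD in mm per operator pass (0 reproduces
#'   identical ratings and ICC = 1).
#' @param seed RNG seed for subject sampling and jitter.
#' @param config a [pipelineConfig()].
#' @return list of class `hyf_repro`: `intra`, `inter` (each a `hyf_icc`),
#'   `ratings` (subjects x 3 matrix), `subjects`.
#' @export
runReproducibility <- function(input, n = 20L, jitterSd = 0.5, seed = 1L,
                               config = pipelineConfig()) {
  src <- .loadCohortInput(input)
  ids <- src$cohort$subject_id
  if (length(ids) < 5L) stop("at least 5 subjects required")
  set.seed(seed)
  sel <- if (length(ids) > n) sort(sample(ids, n)) else ids
  measure <- function(seqs) {
    lax <- seqs[c("LV_endo_2ch", "LA_endo_2ch", "LV_endo_4ch", "LA_endo_4ch")]
    if (any(vapply(lax, is.null, logical(1)))) {
      lax <- .organizeSequences(seqs)[c("LV_endo_2ch", "LA_endo_2ch",
                                        "LV_endo_4ch", "LA_endo_4ch")]
    }
    jit <- lapply(lax, .jitterSequence, sd = jitterSd)
    ac <- areaCurves(jit$LV_endo_2ch, jit$LA_endo_2ch, jit$LV_endo_4ch,
                     jit$LA_endo_4ch, mode = config$area_mode,
                     step = config$station_step)
    hyf(hyfAnalysis(ac$LV, ac$LA, theta = config$diastasis_theta))
  }
  ratings <- matrix(NA_real_, length(sel), 3,
                    dimnames = list(sel, c("op1_pass1", "op1_pass2", "op2")))
  for (i in seq_along(sel)) {
    seqs <- src$getSequences(sel[i])
    for (j in 1:3) ratings[i, j] <- measure(seqs)
  }
  intra <- iccAgreement(ratings[, c("op1_pass1", "op1_pass2")])
  inter <- iccAgreement(ratings[, c("op1_pass1", "op2")])
  structure(list(intra = intra, inter = inter, ratings = ratings,
                 subjects = sel, jitter_sd = jitterSd, config = config),
            class = "hyf_repro")
}
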