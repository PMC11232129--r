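#' @import methods
NULL

.VIEWS <- c("2ch", "4ch", "sax")
.CHAMBERS <- c("LV_endo", "LV_epi", "LA_endo")

#' Time-resolved endocardial or epicardial contour sequence
#'
#' A `ContourSequence` holds the tracked contour of one cardiac chamber in one
#' imaging plane across all frames of the cardiac cycle, as produced by
#' feature-tracking software. Coordinates are in mm in the image plane with y
#' increasing downward; frame 1 is end-diastole (R-wave) under retrospective
#' ECG gating. Atrial contours are closed simple polygons; ventricular
#' long-axis contours are open base-to-apex-to-base curves (`closed = FALSE`)
#' whose basal gap is spanned by the mitral line only when areas are computed.
#'
#' @slot subjectId character subject identifier.
#' @slot view one of `"2ch"`, `"4ch"`, `"sax"`.
#' @slot chamber one of `"LV_endo"`, `"LV_epi"`, `"LA_endo"`.
#' @slot closed logical; whether the stored point list is a closed polygon.
#' @slot rrInterval RR interval in ms (the cycle spans frames 1..n, with the
#'   last frame coinciding with the first).
#' @slot sliceLocation slice position along the LV long axis in mm
#'   (short-axis sequences only, `NA` otherwise).
#' @slot sliceThickness slice thickness in mm (short-axis only).
#' @slot frames list of numeric matrices (n_points x 2), one per frame, in mm.
#'
#' @export
setClass("ContourSequence",
  representation(
    subjectId = "character",
    view = "character",
    chamber = "character",
    closed = "logical",
    rrInterval = "numeric",
    sliceLocation = "numeric",
    sliceThickness = "numeric",
    frames = "list"
  )
)

setValidity("ContourSequence", function(object) {
  msgs <- character()
  if (length(object@view) != 1L || !object@view %in% .VIEWS)
    msgs <- c(msgs, "view must be one of '2ch', '4ch', 'sax'")
  if (length(object@chamber) != 1L || !object@chamber %in% .CHAMBERS)
    msgs <- c(msgs, "chamber must be one of 'LV_endo', 'LV_epi', 'LA_endo'")
  if (length(object@frames) < 1L)
    msgs <- c(msgs, "at least one frame required")
  npts <- vapply(object@frames, function(p) {
    if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p)) return(-1L)
    nrow(p)
  }, integer(1))
  if (any(npts < 0L)) {
    msgs <- c(msgs, "every frame must be a numeric n x 2 matrix")
  } else {
    if (any(npts < 16L))
      msgs <- c(msgs, sprintf("frame %d has fewer than 16 points",
                              which(npts < 16L)[1]))
    if (length(unique(npts)) > 1L)
      msgs <- c(msgs, sprintf(
        "all frames must have the same point count (frame %d has %d, frame 1 has %d)",
        which(npts != npts[1])[1], npts[which(npts != npts[1])[1]], npts[1]))
    dup <- vapply(object@frames, function(p) {
      d <- diff(p)
      any(rowSums(abs(d)) == 0)
    }, logical(1))
    if (any(dup))
      msgs <- c(msgs, sprintf("frame %d contains consecutive duplicate points",
                              which(dup)[1]))
  }
  if (identical(object@view, "sax")) {
    if (!is.finite(object@sliceLocation) || !is.finite(object@sliceThickness))
      msgs <- c(msgs, "short-axis sequences require sliceLocation and sliceThickness")
  } else {
    if (is.finite(object@sliceLocation) || is.finite(object@sliceThickness))
      msgs <- c(msgs, "long-axis sequences must not carry slice metadata")
  }
  if (!is.finite(object@rrInterval) || object@rrInterval <= 0)
    msgs <- c(msgs, "rrInterval must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ContourSequence
#'
#' @param subjectId subject identifier.
#' @param view imaging plane, one of `"2ch"`, `"4ch"`, `"sax"`.
#' @param chamber `"LV_endo"`, `"LV_epi"` or `"LA_endo"`.
#' @param frames list of numeric matrices (n_points x 2), coordinates in mm.
#' @param closed whether the contour is a closed polygon (default: closed for
#'   the left atrium, open for ventricular long-axis contours, closed for
#'   short-axis contours).
#' @param rrInterval RR interval in ms.
#' @param sliceLocation,sliceThickness slice metadata in mm, short-axis only.
#' @return a validated [ContourSequence-class] object.
#' @export
ContourSequence <- function(subjectId, view, chamber, frames,
                            closed = NULL, rrInterval = 1000,
                            sliceLocation = NA_real_,
                            sliceThickness = NA_real_) {
  if (is.null(closed)) {
    closed <- !(chamber %in% c("LV_endo", "LV_epi") && view %in% c("2ch", "4ch"))
  }
  frames <- lapply(frames, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  new("ContourSequence", subjectId = as.character(subjectId), view = view,
      chamber = chamber, closed = isTRUE(closed),
      rrInterval = as.numeric(rrInterval),
      sliceLocation = as.numeric(sliceLocation),
      sliceThickness = as.numeric(sliceThickness), frames = frames)
}

#' Per-frame cross-sectional area curve of one chamber
#'
#' Holds the per-frame maximal transverse diameters (per view), the derived
#' cross-sectional area, and auxiliary per-frame geometry (polygon areas and
#' contour lengths per view) for one chamber over the cardiac cycle.
#'
#' @slot chamber `"LV"` or `"LA"`.
#' @slot areas cross-sectional area in cm2, one per frame.
#' @slot times frame times in ms from the R-wave.
#' @slot mode the diameter-to-area rule used (`"biplane_ellipse"` or
#'   `"single_plane"`).
#' @slot frameData data.frame with one row per frame: `d2`, `d4` (maximal
#'   transverse diameters, mm), `polyarea_2ch`, `polyarea_4ch` (cm2),
#'   `len_2ch`, `len_4ch` (contour lengths, mm; mitral line excluded for open
#'   contours).
#' @export
setClass("AreaCurve",
  representation(chamber = "character", areas = "numeric", times = "numeric",
                 mode = "character", frameData = "data.frame"))

setValidity("AreaCurve", function(object) {
  msgs <- character()
  if (!object@chamber %in% c("LV", "LA"))
    msgs <- c(msgs, "chamber must be 'LV' or 'LA'")
  if (length(object@areas) != length(object@times) ||
      nrow(object@frameData) != length(object@areas))
    msgs <- c(msgs, "areas, times and frameData must cover the same frames")
  if (any(!is.finite(object@areas)) || any(object@areas <= 0))
    msgs <- c(msgs, "areas must be strictly positive")
  if (length(msgs)) msgs else TRUE
})

#' Hydraulic-force analysis result
#'
#' The ventricular-minus-atrial cross-sectional area difference over the
#' cycle, the detected diastasis window, and the scalar hydraulic-force
#' estimate (window mean of the difference, cm2).
#'
#' @slot diffCurve per-frame A_LV - A_LA in cm2.
#' @slot window integer vector of length 2, first and last frame (1-based,
#'   inclusive) of the diastasis window.
#' @slot hyf scalar hydraulic-force estimate in cm2 (may be negative when the
#'   atrium exceeds the ventricle).
#' @slot ePeakFrame,aPeakFrame frames of maximal early and late filling rate.
#' @slot qcFlags character vector of quality-control flags (empty when clean).
#' @export
setClass("HyFResult",
  representation(diffCurve = "numeric", window = "integer", hyf = "numeric",
                 ePeakFrame = "integer", aPeakFrame = "integer",
                 qcFlags = "character"))

setValidity("HyFResult", function(object) {
  msgs <- character()
  if (length(object@window) != 2L || object@window[1] > object@window[2])
    msgs <- c(msgs, "window must be c(t_start, t_end) with t_start <= t_end")
  if (length(object@hyf) != 1L || !is.finite(object@hyf))
    msgs <- c(msgs, "hyf must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' Strain analysis result
#'
#' Scalar LV global strains and LA tri-phasic longitudinal strain together
#' with the per-structure strain-vs-time curves.
#'
#' @slot scalars named numeric: `lv_gls`, `lv_gcs`, `lv_grs` (percent; GLS and
#'   GCS negative, GRS positive), `la_slr`, `la_slc`, `la_slb` (percent,
#'   reservoir/conduit/booster) and `la_residual` (end-of-cycle strain
#'   residual so that `la_slc + la_slb + la_residual == la_slr`).
#' @slot curves named list of per-frame strain curves (percent).
#' @slot tMax frame of maximal LA strain (1-based).
#' @slot tPreA frame of pre-atrial-contraction (end of diastasis, 1-based).
#' @export
setClass("StrainResult",
  representation(scalars = "numeric", curves = "list",
                 tMax = "integer", tPreA = "integer"))

setValidity("StrainResult", function(object) {
  need <- c("la_slr", "la_slc", "la_slb", "la_residual")
  msgs <- character()
  if (!all(need %in% names(object@scalars)))
    msgs <- c(msgs, "scalars must include la_slr, la_slc, la_slb, la_residual")
  else {
    s <- object@scalars
    if (is.finite(s["la_slr"]) &&
        abs(s["la_slr"] - (s["la_slc"] + s["la_slb"] + s["la_residual"])) > 1e-9)
      msgs <- c(msgs, "la_slc + la_slb + la_residual must equal la_slr")
  }
  if (length(msgs)) msgs else TRUE
})
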