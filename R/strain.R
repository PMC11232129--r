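# LV global strains and LA tri-phasic longitudinal strain from tracked
# contour lengths and wall thickness. Lagrangian (engineering) strain
# referenced to frame 1 (end-diastole) throughout.

#' Lagrangian strain curve from a length curve
#'
#' `S(t) = 100 * (L(t) - L(ref)) / L(ref)`, the feature-tracking convention,
#' with the reference at end-diastole by default.
#'
#' @param lengths positive per-frame lengths (mm; any unit, strain is
#'   scale-invariant).
#' @param refFrame reference frame (1-based; default 1 = end-diastole).
#' @return strain in percent per frame, zero at the reference frame.
#' @export
strainCurve <- function(lengths, refFrame = 1L) {
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("lengths must be positive and finite")
  if (refFrame < 1L || refFrame > length(lengths)) stop("invalid reference frame")
  L0 <- lengths[refFrame]
  if (L0 <= 0) stop("zero reference length")
  100 * (lengths - L0) / L0
}

#' LV global longitudinal strain
#'
#' Per-view GLS is the most negative value of the strain curve of the open
#' endocardial contour length (mitral line excluded), referenced to frame 1;
#' the reported GLS is the mean of the 2- and 4-chamber values. With a single
#' view available the single-view value is returned with a `single_view`
#' attribute set.
#'
#' @param lengths2ch,lengths4ch per-frame open endocardial contour lengths in
#'   mm; one may be `NULL`.
#' @return GLS in percent (negative), with attribute `single_view` when only
#'   one view contributed.
#' @export
lvGls <- function(lengths2ch = NULL, lengths4ch = NULL) {
  vals <- c()
  if (!is.null(lengths2ch)) vals <- c(vals, min(strainCurve(lengths2ch)))
  if (!is.null(lengths4ch)) vals <- c(vals, min(strainCurve(lengths4ch)))
  if (!length(vals)) stop("at least one view required")
  out <- mean(vals)
  if (length(vals) == 1L) {
    attr(out, "single_view") <- TRUE
    warning("GLS computed from a single view")
  }
  out
}

.midThird <- function(nSlices) {
  lo <- floor(nSlices / 3) + 1L
  hi <- nSlices - floor(nSlices / 3)
  seq.int(lo, hi)
}

#' LV global circumferential strain
#'
#' Perimeter strain on mid-ventricular short-axis slices (middle third of the
#' stack): per-slice Lagrangian strain curves of the endocardial perimeter are
#' averaged across slices per frame, and GCS is the most negative value.
#'
#' @param saxPerimeters numeric matrix, slices x frames, endocardial
#'   perimeters in mm for the full stack ordered base to apex.
#' @param midThirdOnly restrict to the middle third of slices (default TRUE).
#' @return GCS in percent (negative).
#' @export
lvGcs <- function(saxPerimeters, midThirdOnly = TRUE) {
  saxPerimeters <- as.matrix(saxPerimeters)
  sel <- if (midThirdOnly) .midThird(nrow(saxPerimeters)) else seq_len(nrow(saxPerimeters))
  sc <- t(apply(saxPerimeters[sel, , drop = FALSE], 1, strainCurve))
  min(colMeans(sc))
}

# Radial distance from a center to a polygon boundary along given ray angles.
# The polygon must be star-shaped about the center (true for chamber
# cross-sections); the first positive edge crossing along each ray is used.
.rayRadii <- function(points, center, angles) {
  p <- sweep(as.matrix(points), 2, center)
  n <- nrow(p)
  x1 <- p[, 1]; y1 <- p[, 2]
  x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
  vapply(angles, function(a) {
    ux <- cos(a); uy <- sin(a)
    # solve p1 + s*(p2-p1) = t*u, s in [0,1], t > 0:
    # s = cross(u, p1) / cross(e, u) with cross(a, b) = ax*by - ay*bx
    ex <- x2 - x1; ey <- y2 - y1
    den <- ex * uy - ey * ux
    ok <- abs(den) > 1e-12
    s <- rep(NA_real_, n)
    s[ok] <- -(x1[ok] * uy - y1[ok] * ux) / den[ok]
    tt <- rep(NA_real_, n)
    hit <- ok & s >= -1e-9 & s <= 1 + 1e-9
    tt[hit] <- (x1[hit] + s[hit] * ex[hit]) * ux + (y1[hit] + s[hit] * ey[hit]) * uy
    tt <- tt[is.finite(tt) & tt > 0]
    if (!length(tt)) return(NA_real_)
    min(tt)
  }, numeric(1))
}

#' LV global radial strain
#'
#' Wall thickness at each frame is the mean radial endo-epicardial distance
#' over 64 angular rays cast from the endocardial centroid, averaged over
#' mid-ventricular (middle third) slices; GRS is the peak Lagrangian
#' thickening, `max 100 * (th(t) - th(1)) / th(1)`.
#'
#' @param saxEndo,saxEpi lists of [ContourSequence-class] objects (one per
#'   slice, base to apex, equal slice order and frame counts) for the
#'   endocardial and epicardial short-axis contours.
#' @param nRays number of angular rays (default 64).
#' @param midThirdOnly restrict to the middle third of slices.
#' @return GRS in percent (positive).
#' @export
lvGrs <- function(saxEndo, saxEpi, nRays = 64L, midThirdOnly = TRUE) {
  if (length(saxEndo) != length(saxEpi)) stop("endo/epi slice counts differ")
  sel <- if (midThirdOnly) .midThird(length(saxEndo)) else seq_along(saxEndo)
  nf <- nFrames(saxEndo[[sel[1]]])
  angles <- 2 * pi * (seq_len(nRays) - 1) / nRays
  thick <- matrix(NA_real_, length(sel), nf)
  for (k in seq_along(sel)) {
    sEn <- saxEndo[[sel[k]]]; sEp <- saxEpi[[sel[k]]]
    if (nFrames(sEn) != nf || nFrames(sEp) != nf) stop("frame-count mismatch")
    for (f in seq_len(nf)) {
      ctr <- polygonCentroid(sEn@frames[[f]], check = FALSE)
      rEn <- .rayRadii(sEn@frames[[f]], ctr, angles)
      rEp <- .rayRadii(sEp@frames[[f]], ctr, angles)
      if (any(!is.finite(rEn)) || any(!is.finite(rEp)))
        stop("ray casting failed: contour not star-shaped about the centroid")
      if (any(rEp <= rEn))
        stop("epicardial contour inside endocardial contour at a ray")
      thick[k, f] <- mean(rEp - rEn)
    }
  }
  th <- colMeans(thick)
  max(100 * (th - th[1]) / th[1])
}

#' LA tri-phasic longitudinal strain decomposition
#'
#' Reservoir strain `SL_R = S(t_max)`, conduit strain
#' `SL_C = S(t_max) - S(t_preA)` and booster strain
#' `SL_B = S(t_preA) - S(n)` from the LA strain curve referenced to
#' end-diastole, where `t_max` is the frame of maximal LA strain (ventricular
#' end-systole) and `t_preA` the pre-atrial-contraction frame (here: the last
#' frame of the detected diastasis window). The decomposition satisfies
#' `SL_C + SL_B + residual = SL_R` exactly, with `residual = S(n)` the
#' end-of-cycle strain residual (zero for a periodic curve).
#'
#' @param strainCurve LA strain in percent per frame, `S(1) = 0`.
#' @param tMax frame of maximal strain (1-based), `1 < tMax`.
#' @param tPreA pre-atrial-contraction frame, `tMax < tPreA < n`.
#' @return named numeric: `la_slr`, `la_slc`, `la_slb`, `la_residual`.
#' @export
laPhasicStrain <- function(strainCurve, tMax, tPreA) {
  n <- length(strainCurve)
  if (tMax <= 1L || tMax >= n) stop("tMax must lie strictly inside the cycle")
  if (tPreA <= tMax) stop("tPreA must follow tMax")
  if (tPreA >= n) stop("tPreA must precede the final frame")
  sMax <- strainCurve[tMax]; sPre <- strainCurve[tPreA]; sEnd <- strainCurve[n]
  c(la_slr = sMax, la_slc = sMax - sPre, la_slb = sPre - sEnd,
    la_residual = sEnd)
}

#' Assemble a StrainResult
#'
#' Convenience constructor combining the LV global strains, the LA phasic
#' decomposition and the underlying curves.
#'
#' @param scalars named numeric with `lv_gls`, `lv_gcs`, `lv_grs`, `la_slr`,
#'   `la_slc`, `la_slb`, `la_residual` (missing LV entries allowed as `NA`).
#' @param curves named list of per-frame strain curves.
#' @param tMax,tPreA LA event frames (1-based).
#' @return a [StrainResult-class].
#' @export
StrainResult <- function(scalars, curves = list(), tMax, tPreA) {
  full <- c(lv_gls = NA_real_, lv_gcs = NA_real_, lv_grs = NA_real_)
  full[names(scalars)] <- scalars
  new("StrainResult", scalars = c(full[c("lv_gls", "lv_gcs", "lv_grs")],
                                  scalars[c("la_slr", "la_slc", "la_slb",
                                            "la_residual")]),
      curves = curves, tMax = as.integer(tMax), tPreA = as.integer(tPreA))
}
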