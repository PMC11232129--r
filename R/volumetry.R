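# Chamber volumetry: Simpson summation over the short-axis stack for the LV,
# biplane area-length for the LA, ejection fraction, mass and BSA indexing.

#' LV volume by Simpson summation over the short-axis stack
#'
#' The cavity volume at each frame is the sum over slices of the endocardial
#' cross-sectional area times the slice spacing (thickness + gap). Slices with
#' (near-)zero area at a frame contribute nothing; no partial-slice correction
#' is applied.
#'
#' @param sliceAreas numeric matrix, slices x frames, endocardial areas in cm2
#'   (>= 3 slices).
#' @param thickness slice thickness in mm.
#' @param gap inter-slice gap in mm (default 0).
#' @return numeric vector of volumes in ml, one per frame.
#' @export
lvVolumeSimpson <- function(sliceAreas, thickness, gap = 0) {
  sliceAreas <- as.matrix(sliceAreas)
  if (nrow(sliceAreas) < 3L) stop("at least 3 slices required")
  if (!is.numeric(thickness) || thickness <= 0) stop("thickness must be positive")
  if (gap < 0) stop("gap must be non-negative")
  if (any(!is.finite(sliceAreas)))
    stop("inconsistent frame counts across slices (missing slice areas)")
  colSums(sliceAreas) * (thickness + gap) / 10
}

#' LV mass from epicardial and endocardial volumes
#'
#' Myocardial mass as the epicardial-minus-endocardial shell volume times the
#' myocardial density (1.05 g/ml).
#'
#' @param epiVolume,endoVolume volumes in ml; `epiVolume` must exceed
#'   `endoVolume`.
#' @param density myocardial density in g/ml.
#' @return mass in g.
#' @export
lvMass <- function(epiVolume, endoVolume, density = 1.05) {
  if (any(epiVolume <= endoVolume))
    stop("epicardial volume must exceed endocardial volume")
  (epiVolume - endoVolume) * density
}

#' LA volume by the biplane area-length method
#'
#' `V = (8 / (3 * pi)) * A2 * A4 / L` with the chamber areas from the two
#' orthogonal long-axis views and `L` the shorter of the two long-axis
#' lengths. The rule is exact for ellipsoids.
#'
#' @param area2ch,area4ch chamber areas in the 2- and 4-chamber views, cm2.
#' @param length2ch,length4ch long-axis lengths in the two views, mm.
#' @return volume in ml (vectorized over frames).
#' @export
laVolumeBiplane <- function(area2ch, area4ch, length2ch, length4ch) {
  if (any(c(area2ch, area4ch) <= 0)) stop("non-positive area")
  if (any(c(length2ch, length4ch) <= 0)) stop("non-positive length")
  lmin <- pmin(length2ch, length4ch) / 10 # mm -> cm
  (8 / (3 * pi)) * area2ch * area4ch / lmin
}

#' Ejection fraction
#'
#' @param edv,esv end-diastolic and end-systolic volumes in ml; `esv` may not
#'   exceed `edv` (flagged as an error, never silently clipped).
#' @return ejection fraction in percent.
#' @export
ejectionFraction <- function(edv, esv) {
  if (any(edv <= 0)) stop("edv must be positive")
  if (any(esv < 0) || any(esv > edv)) stop("esv must lie in [0, edv]")
  100 * (edv - esv) / edv
}

#' Body surface area
#'
#' Du Bois (default): `0.007184 * weight^0.425 * height^0.725`; Mosteller:
#' `sqrt(height * weight / 3600)`.
#'
#' @param height height in cm (sanity bounds 100-230).
#' @param weight weight in kg (sanity bounds 25-250).
#' @param formula `"dubois"` or `"mosteller"`.
#' @return body surface area in m2.
#' @export
bodySurfaceArea <- function(height, weight, formula = c("dubois", "mosteller")) {
  formula <- match.arg(formula)
  if (any(height <= 100) || any(height >= 230)) stop("height out of range (100-230 cm)")
  if (any(weight <= 25) || any(weight >= 250)) stop("weight out of range (25-250 kg)")
  switch(formula,
         dubois = 0.007184 * weight^0.425 * height^0.725,
         mosteller = sqrt(height * weight / 3600))
}
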