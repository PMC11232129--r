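# Per-frame planar geometry on tracked contours: areas, centroids, the
# atrioventricular long axis, maximal transverse diameters and contour lengths.

.assertPoints <- function(points, min_n = 3L) {
  points <- as.matrix(points)
  if (!is.numeric(points) || ncol(points) != 2L)
    stop("points must be a numeric n x 2 matrix (mm)")
  if (nrow(points) < min_n)
    stop(sprintf("at least %d points required", min_n))
  if (any(!is.finite(points)))
    stop("points contain non-finite coordinates")
  points
}

.signedAreaMM2 <- function(points) {
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

# Orient polygon so the shoelace signed area is positive.
.orientCCW <- function(points) {
  if (.signedAreaMM2(points) < 0) points[rev(seq_len(nrow(points))), , drop = FALSE]
  else points
}

# Proper-intersection test between all non-adjacent edge pairs (O(n^2),
# vectorized). Touching at shared vertices is allowed.
.isSimplePolygon <- function(points) {
  n <- nrow(points)
  p <- rbind(points, points[1, ])
  a1 <- p[seq_len(n), , drop = FALSE]; a2 <- p[seq_len(n) + 1L, , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j) j > i + 1L &
                       !(i == 1L & j == n)), arr.ind = TRUE)
  if (nrow(idx) == 0) return(TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  cross2 <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a1[j, 1], a1[j, 2])
  d2 <- cross2(a1[i, 1], a1[i, 2], a2[i, 1], a2[i, 2], a2[j, 1], a2[j, 2])
  d3 <- cross2(a1[j, 1], a1[j, 2], a2[j, 1], a2[j, 2], a1[i, 1], a1[i, 2])
  d4 <- cross2(a1[j, 1], a1[j, 2], a2[j, 1], a2[j, 2], a2[i, 1], a2[i, 2])
  !any(d1 * d2 < 0 & d3 * d4 < 0)
}

#' Polygon area by the shoelace rule
#'
#' Area of a simple closed polygon whose vertices are given in mm; the result
#' is returned in cm2. Vertex order is normalized so the signed area is
#' positive.
#'
#' @param points numeric n x 2 matrix of vertices in mm (n >= 3), in order
#'   along the boundary; the closing edge is implicit.
#' @param check validate simplicity and non-degeneracy (default `TRUE`; the
#'   internal pipeline disables it for contours already validated on load).
#' @return polygon area in cm2.
#' @export
polygonArea <- function(points, check = TRUE) {
  points <- .assertPoints(points)
  a <- abs(.signedAreaMM2(points))
  if (check) {
    if (a < 1e-9) stop("degenerate (collinear or zero-area) polygon")
    if (!.isSimplePolygon(points)) stop("self-intersecting polygon")
  }
  a / 100
}

#' Area-weighted polygon centroid
#'
#' Centroid of the enclosed region (not the vertex mean) of a simple polygon,
#' in mm.
#'
#' @inheritParams polygonArea
#' @return numeric length-2 vector, centroid (x, y) in mm.
#' @export
polygonCentroid <- function(points, check = TRUE) {
  points <- .assertPoints(points)
  if (check && !.isSimplePolygon(points)) stop("self-intersecting polygon")
  points <- .orientCCW(points)
  x <- points[, 1]; y <- points[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-9) stop("degenerate polygon: zero area")
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

#' Atrioventricular long axis
#'
#' The long axis is the line through the centers of mass of the ventricular
#' and atrial contours of one frame, oriented from the atrium towards the
#' ventricle. Ventricular open contours are closed by the mitral line before
#' the centroid is taken.
#'
#' @param lvPoints,laPoints numeric n x 2 vertex matrices in mm; the LV
#'   contour may be open (it is closed implicitly).
#' @param check validate polygon simplicity.
#' @return list with `direction` (unit vector, LA to LV), `anchor` (the LA
#'   centroid, mm), `lvCentroid`, `laCentroid`.
#' @export
longAxis <- function(lvPoints, laPoints, check = TRUE) {
  cLV <- polygonCentroid(lvPoints, check = check)
  cLA <- polygonCentroid(laPoints, check = check)
  d <- cLV - cLA
  len <- sqrt(sum(d^2))
  if (len < 1) stop("LV and LA centroids nearly coincide (< 1 mm apart); corrupt contours")
  list(direction = d / len, anchor = cLA, lvCentroid = cLV, laCentroid = cLA)
}

#' Maximal transverse diameter perpendicular to the long axis
#'
#' The maximal chord of the contour along the direction perpendicular to the
#' atrioventricular long axis. Perpendicular section lines ("stations") are
#' scanned along the axis at a fixed step and the intersection span with the
#' polygon boundary is measured at each; the maximum over stations is
#' returned. This mirrors a caliper placed on the image at the widest point
#' of the chamber.
#'
#' @param points numeric n x 2 vertex matrix in mm (treated as closed).
#' @param axis unit direction of the long axis (length-2 numeric), or the
#'   list returned by [longAxis()].
#' @param step station spacing along the axis in mm (default 0.25).
#' @return maximal transverse chord length in mm.
#' @export
maxTransverseDiameter <- function(points, axis, step = 0.25) {
  points <- .assertPoints(points)
  if (is.list(axis)) axis <- axis$direction
  u <- axis / sqrt(sum(axis^2))
  uperp <- c(-u[2], u[1])
  tt <- as.vector(points %*% u)
  ww <- as.vector(points %*% uperp)
  n <- length(tt)
  t1 <- tt; t2 <- c(tt[-1], tt[1])
  w1 <- ww; w2 <- c(ww[-1], ww[1])
  stations <- seq(min(tt), max(tt), by = step)
  if (length(stations) < 2L) stations <- c(min(tt), max(tt))
  # edge x station crossing matrix
  D1 <- outer(t1, stations, `-`)
  D2 <- outer(t2, stations, `-`)
  crossing <- (D1 * D2 <= 0) & (t1 != t2)
  frac <- -D1 / (t2 - t1) # valid where crossing
  W <- w1 + frac * (w2 - w1)
  W[!crossing] <- NA_real_
  rows <- asplit(W, 1)
  hi <- suppressWarnings(do.call(pmax, c(rows, list(na.rm = TRUE))))
  lo <- suppressWarnings(do.call(pmin, c(rows, list(na.rm = TRUE))))
  span <- hi - lo
  span <- span[is.finite(span)]
  if (!length(span)) stop("polygon does not intersect any station (empty projection)")
  max(span)
}

#' Cross-sectional area from transverse diameters
#'
#' Converts the maximal transverse diameters measured on the long-axis views
#' into a chamber cross-sectional area. The default biplane rule treats the
#' cross section as an ellipse with the 2- and 4-chamber diameters as its two
#' axes, `A = pi * d2 * d4 / 4`; the single-plane rule assumes a circular
#' cross section from one diameter.
#'
#' @param d2,d4 maximal transverse diameters in mm (2-chamber and 4-chamber).
#'   In `single_plane` mode only one of the two is required.
#' @param mode `"biplane_ellipse"` (default) or `"single_plane"`.
#' @return cross-sectional area in cm2 (vectorized over frames).
#' @export
crossSectionalArea <- function(d2 = NULL, d4 = NULL,
                               mode = c("biplane_ellipse", "single_plane")) {
  mode <- match.arg(mode)
  if (mode == "biplane_ellipse") {
    if (is.null(d2) || is.null(d4))
      stop("biplane_ellipse mode requires both d2 and d4")
    if (any(d2 <= 0) || any(d4 <= 0)) stop("non-positive diameter")
    pi * d2 * d4 / 4 / 100
  } else {
    d <- if (!is.null(d4)) d4 else d2
    if (is.null(d)) stop("single_plane mode requires one diameter")
    if (any(d <= 0)) stop("non-positive diameter")
    pi * d^2 / 4 / 100
  }
}

#' Contour length
#'
#' Sum of the segment lengths along the contour; the closing segment (for a
#' ventricular contour, the mitral line) is included only when `closed` is
#' `TRUE`.
#'
#' @param points numeric n x 2 matrix of vertices in mm (n >= 2).
#' @param closed include the closing segment.
#' @return length in mm.
#' @export
contourLength <- function(points, closed = FALSE) {
  points <- .assertPoints(points, min_n = 2L)
  d <- sqrt(rowSums(diff(points)^2))
  total <- sum(d)
  if (closed) total <- total + sqrt(sum((points[1, ] - points[nrow(points), ])^2))
  total
}

.timesFromRR <- function(n, rr) (seq_len(n) - 1) * rr / (n - 1)

#' Per-frame chamber area curves from long-axis contour sequences
#'
#' For each frame, the atrioventricular long axis is recomputed from that
#' frame's LV and LA centroids (the centers of mass move during the cycle),
#' the maximal transverse diameter of each chamber is measured perpendicular
#' to it in each available view, and the cross-sectional area is derived with
#' [crossSectionalArea()]. Per-frame polygon areas and contour lengths are
#' carried along for volumetry and strain.
#'
#' @param lv2ch,la2ch,lv4ch,la4ch [ContourSequence-class] objects for the
#'   LV and LA endocardium in the 2- and 4-chamber views. Each supplied view
#'   must include both chambers (the axis needs both centroids). In
#'   `single_plane` mode one view suffices; `biplane_ellipse` requires both.
#' @param mode diameter-to-area rule, see [crossSectionalArea()]. When both
#'   views are supplied in `single_plane` mode the 4-chamber view is used.
#' @param step station spacing for the diameter scan, mm.
#' @return named list with elements `LV` and `LA`, each an
#'   [AreaCurve-class].
#' @export
areaCurves <- function(lv2ch = NULL, la2ch = NULL, lv4ch = NULL, la4ch = NULL,
                       mode = c("biplane_ellipse", "single_plane"),
                       step = 0.25) {
  mode <- match.arg(mode)
  have2 <- !is.null(lv2ch) && !is.null(la2ch)
  have4 <- !is.null(lv4ch) && !is.null(la4ch)
  if ((!is.null(lv2ch)) != (!is.null(la2ch)) ||
      (!is.null(lv4ch)) != (!is.null(la4ch)))
    stop("each supplied view must include both the LV and the LA sequence")
  if (mode == "biplane_ellipse" && !(have2 && have4))
    stop("biplane_ellipse mode requires both the 2ch and 4ch views")
  if (!have2 && !have4) stop("no input sequences")
  seqs <- Filter(Negate(is.null), list(lv2ch, la2ch, lv4ch, la4ch))
  nf <- vapply(seqs, nFrames, integer(1))
  if (length(unique(nf)) != 1L)
    stop("frame-count mismatch across input sequences")
  n <- nf[1]
  rr <- seqs[[1]]@rrInterval

  measureView <- function(lvSeq, laSeq) {
    out <- matrix(NA_real_, n, 8,
                  dimnames = list(NULL, c("d_lv", "d_la", "pa_lv", "pa_la",
                                          "len_lv", "len_la", "ext_lv",
                                          "ext_la")))
    for (f in seq_len(n)) {
      lvP <- lvSeq@frames[[f]]; laP <- laSeq@frames[[f]]
      ax <- longAxis(lvP, laP, check = FALSE)
      out[f, "d_lv"] <- maxTransverseDiameter(lvP, ax, step = step)
      out[f, "d_la"] <- maxTransverseDiameter(laP, ax, step = step)
      out[f, "pa_lv"] <- polygonArea(lvP, check = FALSE)
      out[f, "pa_la"] <- polygonArea(laP, check = FALSE)
      out[f, "len_lv"] <- contourLength(lvP, closed = lvSeq@closed)
      out[f, "len_la"] <- contourLength(laP, closed = laSeq@closed)
      out[f, "ext_lv"] <- .axisExtent(lvP, ax$direction)
      out[f, "ext_la"] <- .axisExtent(laP, ax$direction)
    }
    out
  }
  m2 <- if (have2) measureView(lv2ch, la2ch) else NULL
  m4 <- if (have4) measureView(lv4ch, la4ch) else NULL

  mk <- function(ch) {
    key <- if (ch == "LV") "lv" else "la"
    d2 <- if (have2) m2[, paste0("d_", key)] else rep(NA_real_, n)
    d4 <- if (have4) m4[, paste0("d_", key)] else rep(NA_real_, n)
    area <- if (mode == "biplane_ellipse") crossSectionalArea(d2, d4, mode)
    else crossSectionalArea(d2 = if (have4) NULL else d2,
                            d4 = if (have4) d4 else NULL, mode = mode)
    fd <- data.frame(
      frame = seq_len(n), d2 = d2, d4 = d4,
      polyarea_2ch = if (have2) m2[, paste0("pa_", key)] else NA_real_,
      polyarea_4ch = if (have4) m4[, paste0("pa_", key)] else NA_real_,
      len_2ch = if (have2) m2[, paste0("len_", key)] else NA_real_,
      len_4ch = if (have4) m4[, paste0("len_", key)] else NA_real_,
      axlen_2ch = if (have2) m2[, paste0("ext_", key)] else NA_real_,
      axlen_4ch = if (have4) m4[, paste0("ext_", key)] else NA_real_)
    new("AreaCurve", chamber = ch, areas = as.numeric(area),
        times = .timesFromRR(n, rr), mode = mode, frameData = fd)
  }
  list(LV = mk("LV"), LA = mk("LA"))
}

# Extent of a polygon projected onto a direction (used as the chamber length
# for area-length volumetry).
.axisExtent <- function(points, direction) {
  pr <- as.vector(as.matrix(points) %*% (direction / sqrt(sum(direction^2))))
  max(pr) - min(pr)
}
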