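# The core index: LV - LA cross-sectional area difference over the cycle,
# automatic diastasis detection from the ventricular filling-rate curve, and
# the scalar hydraulic-force estimate.

#' LV minus LA cross-sectional area difference curve
#'
#' @param lvAreas,laAreas per-frame cross-sectional areas in cm2 (numeric
#'   vectors or [AreaCurve-class] objects) with equal frame counts.
#' @return numeric per-frame difference `A_LV(t) - A_LA(t)` in cm2.
#' @export
hyfCurve <- function(lvAreas, laAreas) {
  if (is(lvAreas, "AreaCurve")) lvAreas <- areas(lvAreas)
  if (is(laAreas, "AreaCurve")) laAreas <- areas(laAreas)
  if (length(lvAreas) != length(laAreas))
    stop("LV and LA area curves have different frame counts")
  lvAreas - laAreas
}

# Central-difference derivative on a cyclic curve. Under retrospective gating
# the cycle is closed; when the last frame duplicates the first, the wrap
# skips the duplicate.
.cyclicRate <- function(a, dt) {
  n <- length(a)
  periodicDup <- isTRUE(all.equal(a[1], a[n], tolerance = 1e-9))
  m <- if (periodicDup) n - 1L else n
  core <- a[seq_len(m)]
  nxt <- core[c(seq_len(m)[-1], 1L)]
  prv <- core[c(m, seq_len(m)[-m])]
  d <- (nxt - prv) / (2 * dt)
  if (periodicDup) c(d, d[1]) else d
}

#' Detect the diastasis phase from the LV area curve
#'
#' Diastasis — the mid-diastolic plateau between early filling and atrial
#' contraction, when transmitral flow and the LA-LV pressure gradient are
#' minimal — is located on the ventricular area-rate curve: diastole runs
#' from the area minimum (end-systole) to the cycle end; `dA/dt` is taken by
#' central differences on the cyclic curve; the early-filling rate peak is the
#' maximum of `dA/dt` in the first half of diastole and the atrial-kick peak
#' the maximum after it in the second half; the diastasis window is the
#' longest contiguous run of frames between the two peaks with
#' `|dA/dt| < theta * dA/dt(e-peak)`. If no frame qualifies, the single frame
#' minimizing `|dA/dt|` between the peaks is used and a `short_diastasis`
#' flag set. If no atrial-kick peak is found a `no_a_peak` flag is set and the
#' window falls back to the frame of minimal `|dA/dt|` in late diastole.
#'
#' @param lvAreas per-frame LV cross-sectional area (cm2) or an
#'   [AreaCurve-class].
#' @param times frame times in ms (taken from the AreaCurve when omitted;
#'   defaults to unit spacing).
#' @param theta relative rate threshold (default 0.2).
#' @return list with `window` (integer first/last frame, 1-based, inclusive),
#'   `ePeakFrame`, `aPeakFrame` (NA when absent), `qcFlags`, `rate` (dA/dt).
#' @export
detectDiastasis <- function(lvAreas, times = NULL, theta = 0.2) {
  if (is(lvAreas, "AreaCurve")) {
    if (is.null(times)) times <- frameTimes(lvAreas)
    lvAreas <- areas(lvAreas)
  }
  n <- length(lvAreas)
  if (n < 8L) stop("too few frames to resolve the cardiac phases")
  if (is.null(times)) times <- seq_len(n) - 1
  dt <- mean(diff(times))
  qc <- character()
  es <- which.min(lvAreas)
  if (es <= 1L || es >= n)
    stop(errorCondition(
      "no diastolic limb: the area curve has no interior minimum (monotone or time-reversed curve)",
      class = c("hyforce_qc_error", "error", "condition")))
  rate <- .cyclicRate(lvAreas, dt)
  dia <- es:n
  nd <- length(dia)
  firstHalf <- dia[seq_len(ceiling(nd / 2))]
  ePeak <- firstHalf[which.max(rate[firstHalf])]
  secondHalf <- dia[dia > ePeak & dia >= dia[ceiling(nd / 2)]]
  aPeak <- NA_integer_
  if (length(secondHalf)) {
    cand <- secondHalf[which.max(rate[secondHalf])]
    if (rate[cand] > 0) aPeak <- cand
  }
  if (is.na(aPeak)) {
    qc <- c(qc, "no_a_peak")
    late <- dia[dia > ePeak]
    w <- late[which.min(abs(rate[late]))]
    return(list(window = c(w, w), ePeakFrame = as.integer(ePeak),
                aPeakFrame = NA_integer_, qcFlags = qc, rate = rate))
  }
  between <- if (aPeak - 1L >= ePeak + 1L) seq.int(ePeak + 1L, aPeak - 1L)
             else integer(0)
  if (!length(between)) {
    qc <- c(qc, "short_diastasis")
    w <- if (ePeak + 1L <= n) ePeak + 1L else ePeak
    return(list(window = c(w, w), ePeakFrame = as.integer(ePeak),
                aPeakFrame = as.integer(aPeak), qcFlags = qc, rate = rate))
  }
  thr <- theta * rate[ePeak]
  quiet <- abs(rate[between]) < thr
  if (!any(quiet)) {
    qc <- c(qc, "short_diastasis")
    w <- between[which.min(abs(rate[between]))]
    window <- c(w, w)
  } else {
    r <- rle(quiet)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    window <- c(between[starts[best]], between[ends[best]])
  }
  list(window = as.integer(window), ePeakFrame = as.integer(ePeak),
       aPeakFrame = as.integer(aPeak), qcFlags = qc, rate = rate)
}

#' Scalar hydraulic force over a window
#'
#' Mean of the LV-LA cross-sectional area difference over the given frame
#' window, in cm2. The sign is preserved: the value is negative when the
#' atrial cross section exceeds the ventricular one, the pattern that emerges
#' with aging.
#'
#' @param lvAreas,laAreas per-frame areas (cm2) or [AreaCurve-class] objects.
#' @param window integer first/last frame (1-based, inclusive).
#' @return hydraulic force in cm2.
#' @export
hydraulicForce <- function(lvAreas, laAreas, window) {
  d <- hyfCurve(lvAreas, laAreas)
  if (window[1] < 1L || window[2] > length(d) || window[1] > window[2])
    stop("window outside curve range")
  mean(d[window[1]:window[2]])
}

#' Full hydraulic-force analysis of one subject's area curves
#'
#' Combines [hyfCurve()], [detectDiastasis()] and [hydraulicForce()] into a
#' [HyFResult-class].
#'
#' @param lvCurve,laCurve [AreaCurve-class] objects (or numeric area vectors).
#' @param times frame times in ms (for numeric input).
#' @param theta diastasis rate threshold, see [detectDiastasis()].
#' @return a [HyFResult-class].
#' @export
hyfAnalysis <- function(lvCurve, laCurve, times = NULL, theta = 0.2) {
  det <- detectDiastasis(lvCurve, times = times, theta = theta)
  d <- hyfCurve(lvCurve, laCurve)
  val <- mean(d[det$window[1]:det$window[2]])
  new("HyFResult", diffCurve = d, window = det$window, hyf = val,
      ePeakFrame = det$ePeakFrame,
      aPeakFrame = if (is.na(det$aPeakFrame)) NA_integer_ else det$aPeakFrame,
      qcFlags = det$qcFlags)
}
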