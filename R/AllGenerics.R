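#' Accessors for hyforce S4 containers
#'
#' Small accessor generics: `nFrames()` (number of frames), `chamberName()`,
#' `viewName()`, `contourFrames()` (list of point matrices), `areas()`
#' (cross-sectional areas in cm2), `frameTimes()` (ms), `hyf()` (scalar
#' hydraulic force, cm2), `diastasisWindow()` (first/last frame),
#' `qcFlags()`, and `strains()` (named scalar strain values, percent).
#'
#' @param x a [ContourSequence-class], [AreaCurve-class], [HyFResult-class] or
#'   [StrainResult-class] object as appropriate.
#' @return see the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("chamberName", function(x) standardGeneric("chamberName"))
#' @rdname accessors
#' @export
setGeneric("viewName", function(x) standardGeneric("viewName"))
#' @rdname accessors
#' @export
setGeneric("contourFrames", function(x) standardGeneric("contourFrames"))
#' @rdname accessors
#' @export
setGeneric("areas", function(x) standardGeneric("areas"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("hyf", function(x) standardGeneric("hyf"))
#' @rdname accessors
#' @export
setGeneric("diastasisWindow", function(x) standardGeneric("diastasisWindow"))
#' @rdname accessors
#' @export
setGeneric("qcFlags", function(x) standardGeneric("qcFlags"))
#' @rdname accessors
#' @export
setGeneric("strains", function(x) standardGeneric("strains"))

#' @rdname accessors
setMethod("nFrames", "ContourSequence", function(x) length(x@frames))
#' @rdname accessors
setMethod("nFrames", "AreaCurve", function(x) length(x@areas))
#' @rdname accessors
setMethod("chamberName", "ContourSequence", function(x) x@chamber)
#' @rdname accessors
setMethod("chamberName", "AreaCurve", function(x) x@chamber)
#' @rdname accessors
setMethod("viewName", "ContourSequence", function(x) x@view)
#' @rdname accessors
setMethod("contourFrames", "ContourSequence", function(x) x@frames)
#' @rdname accessors
setMethod("areas", "AreaCurve", function(x) x@areas)
#' @rdname accessors
setMethod("frameTimes", "AreaCurve", function(x) x@times)
#' @rdname accessors
setMethod("hyf", "HyFResult", function(x) x@hyf)
#' @rdname accessors
setMethod("diastasisWindow", "HyFResult", function(x) x@window)
#' @rdname accessors
setMethod("qcFlags", "HyFResult", function(x) x@qcFlags)
#' @rdname accessors
setMethod("strains", "StrainResult", function(x) x@scalars)

setMethod("show", "ContourSequence", function(object) {
  cat(sprintf("ContourSequence: subject %s, %s %s (%s), %d frames x %d points",
              object@subjectId, object@view, object@chamber,
              if (object@closed) "closed" else "open",
              length(object@frames), nrow(object@frames[[1]])))
  if (identical(object@view, "sax"))
    cat(sprintf(", slice %.1f mm (th %.1f mm)",
                object@sliceLocation, object@sliceThickness))
  cat("\n")
})

setMethod("show", "AreaCurve", function(object) {
  cat(sprintf("AreaCurve (%s, %s): %d frames, area %.2f-%.2f cm2\n",
              object@chamber, object@mode, length(object@areas),
              min(object@areas), max(object@areas)))
})

setMethod("show", "HyFResult", function(object) {
  cat(sprintf(
    "HyFResult: HyF = %.3f cm2 over diastasis frames [%d, %d] (%d frames)\n",
    object@hyf, object@window[1], object@window[2],
    object@window[2] - object@window[1] + 1L))
  if (length(object@qcFlags))
    cat("  qc flags:", paste(object@qcFlags, collapse = ", "), "\n")
})

setMethod("show", "StrainResult", function(object) {
  s <- object@scalars
  cat(sprintf("StrainResult: GLS %.1f%%, GCS %.1f%%, GRS %.1f%% | LA SL_R %.1f, SL_C %.1f, SL_B %.1f\n",
              s["lv_gls"], s["lv_gcs"], s["lv_grs"],
              s["la_slr"], s["la_slc"], s["la_slb"]))
})
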