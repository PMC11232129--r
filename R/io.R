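# Reading, validating and writing the contour-sequence JSON format and the
# cohort CSV. The JSON schema is a deliberate artifact definition
# (format_version 1): coordinates in mm, image y-down, frame_index 0-based
# with frame 0 at end-diastole (R-wave).

.schemaStop <- function(msg) {
  stop(errorCondition(msg, class = c("hyforce_schema_error", "error", "condition")))
}
.geometryStop <- function(msg) {
  stop(errorCondition(msg, class = c("hyforce_geometry_error", "error", "condition")))
}

#' Read a contour-sequence file
#'
#' Parses the documented JSON contour format (`format_version: 1`) and
#' validates every invariant: known view/chamber labels, at least 16 points
#' per frame, equal point counts across frames, gapless 0-based frame
#' indices, no consecutive duplicate points, simple (non-self-intersecting)
#' polygons, and slice metadata present exactly for short-axis sequences.
#' Schema violations raise a `hyforce_schema_error`, geometric violations a
#' `hyforce_geometry_error`, each naming the offending sequence and frame.
#'
#' @param path file path.
#' @return list of [ContourSequence-class] objects.
#' @export
readContourFile <- function(path) {
  if (!file.exists(path)) .schemaStop(sprintf("file not found: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) .schemaStop(paste("invalid JSON:",
                                                        conditionMessage(e))))
  if (is.null(doc$format_version) || doc$format_version != 1)
    .schemaStop("missing or unsupported format_version (expected 1)")
  if (is.null(doc$sequences)) .schemaStop("missing field: sequences")
  lapply(seq_along(doc$sequences), function(k) {
    s <- doc$sequences[[k]]
    id <- sprintf("sequence %d (%s/%s/%s)", k,
                  s$subject_id %||% "?", s$view %||% "?", s$chamber %||% "?")
    for (f in c("subject_id", "view", "chamber", "closed", "rr_interval_ms",
                "frames"))
      if (is.null(s[[f]])) .schemaStop(sprintf("%s: missing field '%s'", id, f))
    frames <- lapply(seq_along(s$frames), function(j) {
      fr <- s$frames[[j]]
      if (is.null(fr$frame_index) || is.null(fr$points))
        .schemaStop(sprintf("%s: frame %d missing frame_index or points", id, j))
      if (fr$frame_index != j - 1)
        .schemaStop(sprintf("%s: frame_index values must be 0..n-1 without gaps (got %s at position %d)",
                            id, fr$frame_index, j))
      pts <- do.call(rbind, lapply(fr$points, function(p) {
        if (length(p) != 2) .schemaStop(sprintf("%s: frame %d has a malformed point", id, j))
        as.numeric(p)
      }))
      pts
    })
    seqObj <- tryCatch(
      ContourSequence(s$subject_id, s$view, s$chamber, frames,
                      closed = isTRUE(s$closed),
                      rrInterval = as.numeric(s$rr_interval_ms),
                      sliceLocation = as.numeric(s$slice_location_mm %||% NA),
                      sliceThickness = as.numeric(s$slice_thickness_mm %||% NA)),
      error = function(e) .geometryStop(sprintf("%s: %s", id, conditionMessage(e))))
    for (j in seq_along(frames)) {
      if (!.isSimplePolygon(frames[[j]]))
        .geometryStop(sprintf("%s: self-intersecting polygon at frame %d", id, j - 1))
    }
    seqObj
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write contour sequences to a file
#'
#' Writes the canonical JSON form: fixed key order, coordinates rounded to 4
#' decimals (mm), so identical inputs yield byte-identical files.
#'
#' @param sequences list of [ContourSequence-class] objects (may be empty).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeContourFile <- function(sequences, path) {
  if (is(sequences, "ContourSequence")) sequences <- list(sequences)
  seqList <- lapply(unname(sequences), function(s) {
    stopifnot(is(s, "ContourSequence"))
    validObject(s)
    out <- list(
      subject_id = jsonlite::unbox(s@subjectId),
      view = jsonlite::unbox(s@view),
      chamber = jsonlite::unbox(s@chamber),
      closed = jsonlite::unbox(s@closed),
      rr_interval_ms = jsonlite::unbox(round(s@rrInterval, 4)),
      slice_location_mm = jsonlite::unbox(round(s@sliceLocation, 4)),
      slice_thickness_mm = jsonlite::unbox(round(s@sliceThickness, 4)),
      frames = lapply(seq_along(s@frames), function(j) {
        pts <- round(s@frames[[j]], 4)
        pts[pts == 0] <- 0 # normalize negative zero for canonical output
        list(frame_index = jsonlite::unbox(j - 1L), points = pts)
      })
    )
    if (s@view != "sax") {
      out$slice_location_mm <- NULL
      out$slice_thickness_mm <- NULL
    }
    out
  })
  doc <- list(format_version = jsonlite::unbox(1L), sequences = seqList)
  txt <- jsonlite::toJSON(doc, digits = 4, na = "null")
  writeLines(txt, path, useBytes = TRUE)
  invisible(path)
}

.cohortRequired <- c("subject_id", "age", "sex", "height", "weight", "bmi",
                     "sbp", "dbp", "hr", "E", "A", "Eprime")
.cohortNumeric <- setdiff(.cohortRequired, c("subject_id", "sex"))

#' Read a cohort table
#'
#' Reads the cohort CSV (RFC-4180, UTF-8, "." decimal point), types the
#' columns, preserves unknown columns verbatim, permits missing echo values
#' (empty cells, flagged in the `missing_echo` attribute) and recomputes the
#' derived diastolic-function ratios `E_A = E / A` and `E_Ep = E / Eprime`
#' rather than trusting any supplied values.
#'
#' @param path CSV file path.
#' @return data.frame with one row per subject.
#' @export
readCohortCsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.cohortRequired, names(tab))
  if (length(missing))
    stop(sprintf("cohort table missing required columns: %s",
                 paste(missing, collapse = ", ")))
  dup <- tab$subject_id[duplicated(tab$subject_id)]
  if (length(dup))
    stop(sprintf("duplicate subject_id: %s", paste(unique(dup), collapse = ", ")))
  for (col in .cohortNumeric) {
    v <- tab[[col]]
    if (is.character(v)) {
      v[v == ""] <- NA
      vn <- suppressWarnings(as.numeric(v))
      if (any(!is.na(v) & is.na(vn)))
        stop(sprintf("non-numeric value in numeric column '%s'", col))
      tab[[col]] <- vn
    }
  }
  for (col in c("E", "A", "Eprime")) {
    bad <- !is.na(tab[[col]]) & tab[[col]] <= 0
    if (any(bad))
      stop(sprintf("column '%s' must be positive when present (subject %s)",
                   col, tab$subject_id[which(bad)[1]]))
  }
  tab$E_A <- tab$E / tab$A
  tab$E_Ep <- tab$E / tab$Eprime
  attr(tab, "missing_echo") <-
    tab$subject_id[!stats::complete.cases(tab[, c("E", "A", "Eprime")])]
  tab
}

#' Write a cohort table
#'
#' @param table data.frame as produced by [readCohortCsv()] or
#'   [generateCohort()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeCohortCsv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a subject dataset's contour sequences to a file
#'
#' Serializes all sequences of one synthetic subject (long-axis views and, if
#' present, the short-axis stacks) into a single contour file.
#'
#' @param dataset a `SubjectDataset` from [generateSubject()].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeSubjectContours <- function(dataset, path) {
  seqs <- dataset$sequences
  flat <- c(Filter(function(x) is(x, "ContourSequence"), seqs),
            seqs$sax_endo %||% list(), seqs$sax_epi %||% list())
  writeContourFile(flat, path)
}

#' Write a full cohort dataset to a directory
#'
#' Emits `cohort.csv`, `ground_truth.csv` and one `contours_<subject_id>.json`
#' per subject.
#'
#' @param dataset a `CohortDataset` from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeCohortDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeCohortCsv(dataset$cohort, file.path(dir, "cohort.csv"))
  writeCohortCsv(dataset$groundTruth, file.path(dir, "ground_truth.csv"))
  for (ds in dataset$subjects)
    writeSubjectContours(ds, file.path(dir, sprintf("contours_%s.json",
                                                    ds$params$subject_id)))
  invisible(dir)
}
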