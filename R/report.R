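# Cohort statistics report: age-group comparison tables, univariate and
# adjusted associations of the hydraulic force, rendered as JSON and markdown.

.fmtP <- function(p, floor = 1e-4) {
  ifelse(is.na(p), "na",
         ifelse(p < floor, sprintf("<%.4f", floor), sprintf("%.4f", p)))
}

.meanSd <- function(v) {
  v <- v[!is.na(v)]
  if (!length(v)) return("na")
  sprintf("%.2f ± %.2f", mean(v), stats::sd(v))
}

.table1Vars <- c("age", "bmi", "bsa", "hr", "sbp", "dbp", "E", "A", "E_A",
                 "Eprime", "E_Ep", "lv_massi", "lv_edvi", "lv_esvi", "lv_ef",
                 "la_edvi", "la_esvi", "la_ef")
.table2Vars <- c("lv_gls", "lv_gcs", "lv_grs", "la_slr", "la_slc", "la_slb",
                 "lv_area_diastasis", "la_area_diastasis", "hyf")
.table3Vars <- c("age", "Eprime", "E_A", "E_Ep", "la_slc")

#' Build the cohort statistics report
#'
#' Assembles the study-style summary from an analyzed cohort table: per-group
#' means and SDs with Wilcoxon p for the younger (< 50 years) and older
#' (>= 50) groups; univariate regressions of the hydraulic force on age and
#' the diastolic-function indices; and age/sex/BMI-adjusted models for E/A and
#' the atrial conduit strain (both the full-model and the predictor's partial
#' R2 are reported). P-values are floored at `<0.0001` in the markdown
#' rendering. With a single-age-group cohort the group comparison is marked
#' not applicable and the regressions still run.
#'
#' @param results analyzed cohort table (one row per subject, as produced by
#'   [runCohort()]), containing at least `age` and `hyf` plus whatever derived
#'   columns are available.
#' @param alpha significance level used for flagging (default 0.05).
#' @param holm apply Holm correction to the reported association p-values
#'   (default FALSE, matching uncorrected reporting).
#' @return list of class `hyf_report` with elements `groups`,
#'   `group_comparison`, `associations`, `adjusted`, `meta`.
#' @export
buildReport <- function(results, alpha = 0.05, holm = FALSE) {
  if (!all(c("age", "hyf") %in% names(results)))
    stop("results must contain columns: age, hyf")
  g <- splitAgeGroups(results)
  comparable <- nrow(g$G1) > 0 && nrow(g$G2) > 0

  compRows <- lapply(intersect(c(.table1Vars, .table2Vars), names(results)),
                     function(v) {
    p <- if (comparable && sum(!is.na(g$G1[[v]])) > 0 &&
             sum(!is.na(g$G2[[v]])) > 0)
      wilcoxonRankSum(g$G1[[v]], g$G2[[v]])$p_value else NA_real_
    list(variable = v,
         g1_mean = mean(g$G1[[v]], na.rm = TRUE),
         g1_sd = stats::sd(g$G1[[v]], na.rm = TRUE),
         g2_mean = mean(g$G2[[v]], na.rm = TRUE),
         g2_sd = stats::sd(g$G2[[v]], na.rm = TRUE),
         p_value = p)
  })
  compP <- vapply(compRows, function(r) r$p_value, numeric(1))
  if (holm) {
    adj <- stats::p.adjust(compP, method = "holm")
    for (i in seq_along(compRows)) compRows[[i]]$p_value <- adj[i]
  }

  assoc <- list()
  for (v in intersect(.table3Vars, names(results))) {
    assoc[[v]] <- tryCatch(linregUnivariate(results[[v]], results$hyf),
                           error = function(e) NULL)
  }
  if (holm) {
    ps <- vapply(assoc, function(a) if (is.null(a)) NA_real_ else a$p_value,
                 numeric(1))
    adj <- stats::p.adjust(ps, method = "holm")
    for (i in seq_along(assoc)) if (!is.null(assoc[[i]]))
      assoc[[i]]$p_value <- adj[i]
  }

  adjusted <- list()
  adjCov <- intersect(c("age", "sex", "bmi"), names(results))
  if (length(adjCov) == 3) {
    for (v in intersect(c("E_A", "la_slc"), names(results))) {
      adjusted[[v]] <- tryCatch(
        linregAdjusted(results$hyf, results[[v]], results[, adjCov]),
        error = function(e) NULL)
    }
  }

  structure(list(
    groups = list(n_g1 = nrow(g$G1), n_g2 = nrow(g$G2),
                  comparable = comparable),
    group_comparison = compRows,
    associations = assoc,
    adjusted = adjusted,
    meta = list(alpha = alpha, holm = holm, n = nrow(results),
                group_rule = "G1: age < 50; G2: age >= 50")),
    class = "hyf_report")
}

#' Render a report as markdown
#'
#' @param report a `hyf_report` from [buildReport()].
#' @return character scalar, the markdown text (deterministic for identical
#'   inputs).
#' @export
reportMarkdown <- function(report) {
  L <- character()
  add <- function(...) L <<- c(L, sprintf(...))
  add("# Cohort statistics report")
  add("")
  add("Subjects analyzed: %d (G1 n = %d, G2 n = %d; %s)",
      report$meta$n, report$groups$n_g1, report$groups$n_g2,
      report$meta$group_rule)
  add("")
  add("## Age-group comparison")
  add("")
  if (!report$groups$comparable) {
    add("Not applicable: the cohort contains a single age group.")
  } else {
    add("| Variable | G1 (mean ± SD) | G2 (mean ± SD) | Wilcoxon p |")
    add("|---|---|---|---|")
    for (r in report$group_comparison)
      add("| %s | %.2f ± %.2f | %.2f ± %.2f | %s |",
          r$variable, r$g1_mean, r$g1_sd, r$g2_mean, r$g2_sd,
          .fmtP(r$p_value))
  }
  add("")
  add("## Univariate associations of HyF")
  add("")
  add("| Predictor | R2 | slope | p |")
  add("|---|---|---|---|")
  for (v in names(report$associations)) {
    a <- report$associations[[v]]
    if (is.null(a)) next
    add("| %s | %.3f | %.4f | %s |", v, a$r_squared, a$slope,
        .fmtP(a$p_value))
  }
  add("")
  add("## Adjusted models (age, sex, BMI)")
  add("")
  if (!length(report$adjusted)) {
    add("Not computed (age, sex and BMI columns required).")
  } else {
    add("| Predictor | full-model R2 | partial R2 | predictor p |")
    add("|---|---|---|---|")
    for (v in names(report$adjusted)) {
      a <- report$adjusted[[v]]
      if (is.null(a)) next
      add("| %s | %.3f | %.3f | %s |", v, a$full_r_squared,
          a$partial_r_squared, .fmtP(a$p_value))
    }
  }
  add("")
  paste(L, collapse = "\n")
}

#' Write a report to disk
#'
#' Emits `report.json` and `report.md` into a directory.
#'
#' @param report a `hyf_report`.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, na = "null",
                       pretty = TRUE)
  writeLines(reportMarkdown(report), file.path(dir, "report.md"),
             useBytes = TRUE)
  invisible(dir)
}
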