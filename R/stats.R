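# Cohort statistics: age-group split, Wilcoxon rank-sum comparison,
# univariate and covariate-adjusted linear models, and intraclass correlation
# for reproducibility, with the category thresholds used in the clinical
# reporting tradition.

#' Split a cohort into age groups
#'
#' G1: age < 50 years; G2: age >= 50 years (50 exactly falls in G2).
#'
#' @param cohort data.frame with an `age` column.
#' @return list with data.frames `G1` and `G2`.
#' @export
splitAgeGroups <- function(cohort) {
  if (!"age" %in% names(cohort) || any(is.na(cohort$age)))
    stop("cohort must carry a complete 'age' column")
  list(G1 = cohort[cohort$age < 50, , drop = FALSE],
       G2 = cohort[cohort$age >= 50, , drop = FALSE])
}

#' Wilcoxon rank-sum test (unpaired)
#'
#' Midranks for ties; exact two-sided p by enumeration when the combined
#' sample size is at most 12 and there are no ties, otherwise the normal
#' approximation with tie and continuity correction (the behaviour of
#' [stats::wilcox.test()], which performs the computation).
#'
#' @param x,y numeric samples (each non-empty).
#' @return list with `statistic` (Mann-Whitney U), `rank_sum` (rank sum of
#'   `x`), `p_value` (two-sided), `exact` (logical).
#' @export
wilcoxonRankSum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty group")
  exact <- (length(x) + length(y) <= 12) && !anyDuplicated(c(x, y))
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(statistic = unname(wt$statistic),
       rank_sum = unname(wt$statistic) + length(x) * (length(x) + 1) / 2,
       p_value = wt$p.value, exact = exact)
}

#' Univariate linear regression
#'
#' Ordinary least squares of `y` on `x` with pairwise deletion of missing
#' values; `R2` equals the squared Pearson correlation; the p-value is the
#' two-sided slope t-test.
#'
#' @param x,y numeric vectors of equal length.
#' @return list of class `hyf_regression`: `slope`, `intercept`, `r_squared`,
#'   `p_value`, `n`.
#' @export
linregUnivariate <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("fewer than 3 complete pairs")
  if (stats::sd(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "hyf_regression")
}

.sexIndicator <- function(sex) {
  if (is.numeric(sex)) return(sex)
  s <- toupper(as.character(sex))
  if (!all(s %in% c("M", "F"))) stop("sex must be coded M/F or numeric")
  ifelse(s == "M", 1, 0) # F = 0, M = 1
}

#' Covariate-adjusted linear regression
#'
#' OLS of `y` on the predictor plus the adjusters (by default age, sex as an
#' F = 0 / M = 1 indicator, and BMI). Reports the full-model R2, the
#' predictor's partial p-value, the partial R2 of the predictor (extra sum of
#' squares over the adjusters-only model), and each covariate's p-value. A
#' rank-deficient design raises an error naming the collinear column.
#'
#' @param y response.
#' @param predictor numeric predictor of interest.
#' @param adjusters data.frame of adjustment covariates (a `sex` column is
#'   recoded to the binary indicator).
#' @return list of class `hyf_regression_adj`: `slope`, `p_value` (predictor
#'   partial p), `full_r_squared`, `partial_r_squared`, `covariate_p`, `n`.
#' @export
linregAdjusted <- function(y, predictor, adjusters) {
  adjusters <- as.data.frame(adjusters)
  if ("sex" %in% names(adjusters))
    adjusters$sex <- .sexIndicator(adjusters$sex)
  df <- cbind(data.frame(.y = y, .pred = predictor), adjusters)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  k <- ncol(df) - 1L
  if (nrow(df) < max(6L, k + 2L)) stop("too few complete cases")
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    bad <- names(cf)[is.na(cf)]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")))
  }
  sm <- summary(fit)
  reduced <- stats::lm(.y ~ ., data = df[, setdiff(names(df), ".pred"),
                                         drop = FALSE])
  sseF <- sum(stats::residuals(fit)^2)
  sseR <- sum(stats::residuals(reduced)^2)
  covP <- sm$coefficients[-(1:2), 4]
  structure(list(slope = unname(cf[".pred"]),
                 p_value = sm$coefficients[".pred", 4],
                 full_r_squared = sm$r.squared,
                 partial_r_squared = (sseR - sseF) / sseR,
                 covariate_p = covP, n = nrow(df)),
            class = "hyf_regression_adj")
}

#' Intraclass correlation coefficient (two-way random, absolute agreement,
#' single measure)
#'
#' ICC(2,1) from the two-way ANOVA mean squares:
#' `(MS_R - MS_E) / (MS_R + (k-1) MS_E + (k/n) (MS_C - MS_E))` with `MS_R` the
#' between-subject, `MS_C` the between-rater and `MS_E` the residual mean
#' square, `n` subjects and `k` raters. The category follows the printed
#' bands: excellent (> 0.74), good (0.60-0.74), moderate (0.40-0.59), poor
#' (< 0.40).
#'
#' @param ratings numeric matrix, subjects x raters, complete.
#' @return list of class `hyf_icc`: `icc`, `model`, `category`, `n_subjects`,
#'   `n_raters`, `ms` (the three mean squares).
#' @export
iccAgreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (k < 2) stop("at least 2 raters required")
  if (any(is.na(ratings))) stop("missing cells in the rating matrix")
  if (n < 5) warning("fewer than 5 subjects: ICC estimate is unstable")
  d <- data.frame(value = as.vector(ratings),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  ms <- summary(stats::aov(value ~ subject + rater, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  structure(list(icc = unname(icc),
                 model = "two-way random effects, absolute agreement, single measure (ICC(2,1))",
                 category = iccClassify(icc), n_subjects = n, n_raters = k,
                 ms = c(MS_R = unname(msr), MS_C = unname(msc),
                        MS_E = unname(mse))),
            class = "hyf_icc")
}

#' Classify an ICC value
#'
#' Excellent above 0.74; good on \[0.60, 0.74\] (boundaries inclusive);
#' moderate on \[0.40, 0.60); poor below 0.40.
#'
#' @param icc a finite ICC value.
#' @return character category.
#' @export
iccClassify <- function(icc) {
  if (!is.finite(icc)) stop("icc must be finite")
  if (icc > 0.74) "excellent"
  else if (icc >= 0.60) "good"
  else if (icc >= 0.40) "moderate"
  else "poor"
}
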