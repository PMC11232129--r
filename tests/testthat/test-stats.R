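test_that("splitAgeGroups uses the 50-year boundary with 50 in G2", {
  co <- data.frame(age = c(20, 49.9, 50, 50.1, 80), id = 1:5)
  g <- splitAgeGroups(co)
  expect_equal(g$G1$id, 1:2)
  expect_equal(g$G2$id, 3:5)
  expect_error(splitAgeGroups(data.frame(id = 1)), "age")
  expect_error(splitAgeGroups(data.frame(age = c(1, NA))), "complete")
})

test_that("exact Wilcoxon p matches hand calculation and exhaustive enumeration", {
  # [1,2] vs [3,4]: most extreme of C(4,2)=6 assignments, two-sided p = 2/6
  w <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p_value, 1 / 3)
  expect_equal(w$statistic, 0)
  expect_equal(w$rank_sum, 3)
  set.seed(31)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    v <- sample(1:50, nx + ny)  # distinct: no ties
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    w <- wilcoxonRankSum(x, y)
    expect_true(w$exact)
    expect_equal(w$p_value, oracleWilcoxExact(x, y), tolerance = 1e-12)
  }
})

test_that("Wilcoxon falls back to the corrected normal approximation", {
  w <- wilcoxonRankSum(c(1, 2, 2, 4), c(3, 5, 6, 7))  # ties present
  expect_false(w$exact)
  big <- wilcoxonRankSum(rnorm(20), rnorm(20))
  expect_false(big$exact)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "empty")
})

test_that("univariate regression matches closed forms", {
  set.seed(2)
  x <- rnorm(60); y <- 2 - 1.5 * x + rnorm(60, 0, 0.5)
  fit <- linregUnivariate(x, y)
  expect_equal(fit$r_squared, stats::cor(x, y)^2, tolerance = 1e-12)
  expect_equal(fit$slope, stats::cov(x, y) / stats::var(x), tolerance = 1e-12)
  expect_equal(fit$n, 60)
  # exact fit
  f2 <- suppressWarnings(linregUnivariate(1:10, 3 + 2 * (1:10)))
  expect_equal(f2$slope, 2); expect_equal(f2$r_squared, 1)
  expect_error(linregUnivariate(rep(1, 10), rnorm(10)), "zero variance")
  expect_error(linregUnivariate(1:2, 1:2), "fewer than 3")
})

test_that("regression p-values are uniform under the null", {
  set.seed(99)
  ps <- replicate(200, linregUnivariate(rnorm(25), rnorm(25))$p_value)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("adjusted model recovers a known slope and reports partial R2", {
  set.seed(17)
  hits <- 0
  for (rep in 1:100) {
    n <- 80
    age <- runif(n, 20, 80)
    sex <- sample(c("M", "F"), n, replace = TRUE)
    bmi <- rnorm(n, 24, 3)
    pred <- 0.5 * age + rnorm(n, 0, 5)
    y <- 1.5 * pred - 0.2 * age + 0.8 * (sex == "M") + 0.1 * bmi + rnorm(n)
    fit <- linregAdjusted(y, pred, data.frame(age = age, sex = sex, bmi = bmi))
    # independent CI for the coverage check, straight from lm
    df2 <- data.frame(y = y, pred = pred, age = age,
                      sex = ifelse(sex == "M", 1, 0), bmi = bmi)
    cf <- summary(stats::lm(y ~ pred + age + sex + bmi, df2))$coefficients
    lo <- cf["pred", 1] - stats::qt(0.975, n - 5) * cf["pred", 2]
    hi <- cf["pred", 1] + stats::qt(0.975, n - 5) * cf["pred", 2]
    if (lo <= 1.5 && 1.5 <= hi) hits <- hits + 1
    expect_equal(fit$slope, unname(cf["pred", 1]), tolerance = 1e-10)
    expect_gte(fit$partial_r_squared, 0)
    expect_lte(fit$partial_r_squared, 1)
  }
  expect_gte(hits, 90)
})

test_that("adjusted model refuses rank-deficient designs by name", {
  set.seed(3)
  n <- 30
  age <- runif(n, 20, 80)
  adj <- data.frame(age = age, sex = sample(c("M", "F"), n, TRUE),
                    bmi = 2 * age)   # collinear with age
  expect_error(linregAdjusted(rnorm(n), rnorm(n), adj), "rank-deficient")
  expect_error(linregAdjusted(rnorm(4), rnorm(4), adj[1:4, ]), "too few")
})

test_that("ICC(2,1) matches the brute-force ANOVA oracle", {
  set.seed(13)
  for (i in 1:15) {
    n <- sample(6:25, 1); k <- sample(2:4, 1)
    subj <- rnorm(n, 0, 2)
    rater <- rnorm(k, 0, 0.5)
    m <- outer(subj, rep(1, k)) + outer(rep(1, n), rater) +
      matrix(rnorm(n * k, 0, 0.7), n, k)
    got <- iccAgreement(m)
    expect_equal(got$icc, oracleIcc21(m), tolerance = 1e-10)
    expect_equal(got$n_subjects, n); expect_equal(got$n_raters, k)
  }
})

test_that("ICC edge behavior: identical ratings, offsets, validation", {
  set.seed(8)
  v <- rnorm(12, 10, 2)
  expect_equal(iccAgreement(cbind(v, v))$icc, 1, tolerance = 1e-12)
  # a constant rater offset lowers ABSOLUTE-agreement ICC
  withOffset <- iccAgreement(cbind(v, v + 2))$icc
  expect_lt(withOffset, 1)
  expect_lt(withOffset, iccAgreement(cbind(v, v + 0.1))$icc)
  expect_error(iccAgreement(matrix(v, ncol = 1)), "2 raters")
  m <- cbind(v, v); m[3, 1] <- NA
  expect_error(iccAgreement(m), "missing")
  expect_warning(iccAgreement(matrix(rnorm(8), 4, 2)), "fewer than 5")
})

test_that("ICC categories follow the printed bands", {
  expect_equal(iccClassify(0.82), "excellent")
  expect_equal(iccClassify(0.80), "excellent")
  expect_equal(iccClassify(0.74), "good")
  expect_equal(iccClassify(0.60), "good")
  expect_equal(iccClassify(0.5), "moderate")
  expect_equal(iccClassify(0.39), "poor")
  expect_error(iccClassify(NaN), "finite")
})
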