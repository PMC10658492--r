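# simple simulation helper: predictions spread over (0,1), outcome drawn
# from a possibly shifted/scaled logistic model
sim_cohort <- function(n, a = 0, b = 1, seed = 1) {
  set.seed(seed)
  p <- plogis(rnorm(n, 0, 1.2))
  y <- rbinom(n, 1, plogis(a + b * qlogis(p)))
  list(p = p, y = y)
}

test_that("recalibration recovers (0, 1) on well-calibrated data", {
  s <- sim_cohort(5000, seed = 101)
  r <- recalibrate(s$p, s$y)
  expect_lt(abs(r$a$estimate), 0.1)
  expect_lt(abs(r$b$estimate - 1), 0.1)
  expect_true(r$a$ci[1] <= 0 && 0 <= r$a$ci[2])
  expect_true(r$b_vs_1$p > 0.05)
})

test_that("recalibration recovers an injected calibration-in-the-large offset", {
  s <- sim_cohort(5000, a = 0.7, seed = 102)
  r <- recalibrate(s$p, s$y)
  expect_true(r$a$ci[1] <= 0.7 && 0.7 <= r$a$ci[2])
  expect_true(r$b$ci[1] <= 1 && 1 <= r$b$ci[2])
  # positive a reads as underestimation, negative as overestimation
  expect_match(r$interpretation, "underestimates")
  s2 <- sim_cohort(5000, a = -0.7, seed = 103)
  expect_match(recalibrate(s2$p, s2$y)$interpretation, "overestimates")
})

test_that("recalibration rejects degenerate cohorts", {
  expect_error(recalibrate(rep(0.5, 100), rbinom(100, 1, 0.5)),
               "unidentifiable")
  expect_error(recalibrate(runif(50), rep(1, 50)), "both outcome classes")
  expect_error(recalibrate(runif(10), rep(0:1, 4)), "equal length")
})

test_that("intercept-only update fixes the slope at 1", {
  s <- sim_cohort(2000, a = -1, seed = 104)
  r <- recalibrate(s$p, s$y, fix_slope = TRUE)
  expect_identical(r$b$estimate, 1)
  expect_true(r$a$ci[1] <= -1 && -1 <= r$a$ci[2])
})

test_that("joint recalibration covers (0, 1) in at least 90% of replicates", {
  hits <- 0L
  for (i in 1:100) {
    s <- sim_cohort(2000, seed = 200 + i)
    r <- recalibrate(s$p, s$y)
    if (r$a$ci[1] <= 0 && 0 <= r$a$ci[2] &&
        r$b$ci[1] <= 1 && 1 <= r$b$ci[2]) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("Hosmer-Lemeshow is zero when observed equals expected in every bin", {
  # ten blocks of 20 records at p = k/20; each block's observed case count is
  # exactly its summed prediction (an integer), so every decile fits perfectly
  qs <- (1:10) / 20
  p <- rep(qs, each = 20)
  y <- unlist(lapply(qs, function(q) rep(c(1, 0), c(20 * q, 20 - 20 * q))))
  hl <- hosmer_lemeshow(p, y)
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_identical(hl$df, 8L)
  expect_gt(hl$p, 0.999)
})

test_that("Hosmer-Lemeshow merges degenerate bins with a warning", {
  set.seed(5)
  p <- c(rep(0, 30), runif(70, 0.2, 0.8))
  y <- rbinom(100, 1, p)
  expect_warning(hl <- hosmer_lemeshow(p, y), "merging")
  expect_lt(hl$df, 8L)
  expect_error(hosmer_lemeshow(runif(10), rbinom(10, 1, 0.5), groups = 2), "3 groups")
})

test_that("Hosmer-Lemeshow holds its type-I error under a correct model", {
  rejections <- 0L
  for (i in 1:200) {
    s <- sim_cohort(1000, seed = 500 + i)
    if (hosmer_lemeshow(s$p, s$y)$p < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / 200
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.11)
})

test_that("calibration table reports group means and observed proportions", {
  s <- sim_cohort(500, seed = 7)
  tab <- calibration_table(s$p, s$y)
  expect_identical(nrow(tab), 10L)
  expect_equal(sum(tab$n), 500)
  expect_equal(sum(tab$observed_cases), sum(s$y))
  expect_true(!is.unsorted(tab$mean_predicted))
})

test_that("c-statistic equals the exhaustive pair count", {
  expect_equal(c_statistic(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$c_statistic, 1)
  expect_equal(c_statistic(rep(0.4, 10), rep(0:1, 5))$c_statistic, 0.5)
  expect_equal(c_statistic(c(0.9, 0.4, 0.5, 0.2), c(1, 1, 0, 0))$c_statistic, 0.75)
  set.seed(13)
  for (n in c(6, 25, 80, 200)) {
    p <- sample(seq(0.05, 0.95, by = 0.05), n, replace = TRUE)  # ties likely
    y <- rbinom(n, 1, p)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(c_statistic(p, y)$c_statistic, pair_count_c(p, y),
                 tolerance = 1e-12)
  }
  expect_error(c_statistic(runif(10), rep(1, 10)), "both outcome classes")
})

test_that("DeLong interval agrees with an independent implementation", {
  set.seed(19)
  p <- runif(150)
  y <- rbinom(150, 1, p)
  d <- c_statistic(p, y)
  ref <- pROC::ci.auc(pROC::roc(y, p, quiet = TRUE), method = "delong")
  expect_equal(d$c_statistic, as.numeric(pROC::auc(pROC::roc(y, p, quiet = TRUE))),
               tolerance = 1e-12)
  expect_equal(d$ci[1], ref[1], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(d$ci[2], ref[3], tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("bootstrap interval is seeded and sane", {
  set.seed(23)
  p <- runif(120); y <- rbinom(120, 1, p)
  d1 <- c_statistic(p, y, ci_method = "bootstrap", B = 500, seed = 3)
  d2 <- c_statistic(p, y, ci_method = "bootstrap", B = 500, seed = 3)
  expect_identical(d1$ci, d2$ci)
  expect_true(d1$ci[1] < d1$c_statistic && d1$c_statistic < d1$ci[2])
})

test_that("discrimination bands respect the stated cut-points", {
  expect_identical(cushval:::c_band(0.65), "poor")
  expect_identical(cushval:::c_band(0.7), "acceptable")
  expect_identical(cushval:::c_band(0.79), "acceptable")
  expect_identical(cushval:::c_band(0.80), "excellent")
  expect_identical(cushval:::c_band(0.90), "excellent")
  expect_identical(cushval:::c_band(0.901), "outstanding")
})

test_that("ROC curve is a staircase whose area equals the c-statistic", {
  # perfect separation passes through (0, 1)
  roc <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_true(any(roc$sensitivity == 1 & roc$one_minus_specificity == 0))
  # all predictions tied: two points, area 1/2
  roc2 <- roc_curve(rep(0.3, 8), rep(0:1, 4))
  expect_identical(nrow(roc2), 2L)
  expect_equal(attr(roc2, "auc"), 0.5)
  set.seed(29)
  p <- sample(seq(0.1, 0.9, by = 0.1), 50, replace = TRUE)
  y <- rbinom(50, 1, p)
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  roc3 <- roc_curve(p, y)
  expect_lt(abs(attr(roc3, "auc") - c_statistic(p, y)$c_statistic), 1e-12)
  expect_true(!is.unsorted(roc3$sensitivity))
  expect_true(!is.unsorted(roc3$one_minus_specificity))
  expect_equal(roc3$sensitivity[nrow(roc3)], 1)
})

test_that("threshold diagnostics count the confusion matrix correctly", {
  scores <- c(3, 2, 1, 1, 0)
  y <- c(1, 1, 1, 0, 0)
  d <- threshold_diagnostics(scores, y, 2)
  expect_identical(c(d$tp, d$fn, d$fp, d$tn), c(2L, 1L, 0L, 2L))
  expect_equal(d$sensitivity, 2 / 3)
  expect_equal(d$specificity, 1)
  expect_equal(d$ppv, 1)
  expect_equal(d$npv, 2 / 3)

  # below the minimum score everyone is predicted positive, so NPV has a
  # zero denominator and is reported missing
  expect_warning(low <- threshold_diagnostics(scores, y, -20), "NPV undefined")
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  expect_true(is.na(low$npv))

  expect_warning(none <- threshold_diagnostics(scores, y, 99), "PPV undefined")
  expect_true(is.na(none$ppv))
  expect_error(threshold_diagnostics(NULL, y, 2), "required")
})

test_that("sensitivity falls and specificity rises with the threshold", {
  set.seed(37)
  scores <- sample(-13:10, 300, replace = TRUE)
  y <- rbinom(300, 1, plogis(scores / 4))
  prev <- NULL
  for (t in -13:11) {
    d <- suppressWarnings(threshold_diagnostics(scores, y, t))
    if (!is.null(prev)) {
      expect_lte(d$sensitivity, prev$sensitivity)
      expect_gte(d$specificity, prev$specificity)
    }
    prev <- d
  }
})
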