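# Model-performance machinery: logistic recalibration, Hosmer-Lemeshow,
# decile calibration table, c-statistic / ROC, threshold diagnostics.

validate_cohort_vectors <- function(predicted, observed, need_both_classes = TRUE) {
  predicted <- as.numeric(predicted)
  observed <- as.integer(observed)
  if (length(predicted) != length(observed)) {
    stop("predicted and observed must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) stop("need at least 2 records", call. = FALSE)
  if (any(is.na(predicted)) || any(is.na(observed))) {
    stop("missing values in predicted or observed", call. = FALSE)
  }
  if (!all(observed %in% c(0L, 1L))) {
    stop("observed outcomes must be binary 0/1", call. = FALSE)
  }
  if (need_both_classes && length(unique(observed)) < 2) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  list(predicted = predicted, observed = observed)
}

# Wald CI and two-sided p for one glm coefficient
.wald <- function(estimate, se, null = 0, conf = 0.95) {
  z <- (estimate - null) / se
  list(z = z, p = 2 * pnorm(-abs(z)),
       ci = estimate + c(-1, 1) * qnorm(1 - (1 - conf) / 2) * se)
}

#' Logistic recalibration: calibration-in-the-large and calibration slope
#'
#' Fits the recalibration model `logit(y) = a + b * logit(yhat)` by maximum
#' likelihood, where `y` is the observed outcome and `yhat` the predicted
#' probability. The intercept `a` is the calibration-in-the-large (ideal
#' value 0; `a < 0` means the model overestimates the odds, `a > 0`
#' underestimation) and `b` is the calibration slope (ideal value 1;
#' `0 < b < 1` means predictions vary too much, `b > 1` too little).
#'
#' Wald 95% confidence intervals and two-sided p-values are attached. For
#' the slope both null hypotheses are tested and labelled: `b = 0` (is the
#' predictor informative at all) and `b = 1` (does the slope deviate from
#' ideal). Predicted probabilities are clipped into `[0.001, 0.999]` before
#' the logit transform.
#'
#' @param predicted numeric vector of predicted probabilities.
#' @param observed binary outcome vector (1 = case).
#' @param fix_slope if `TRUE`, fit the intercept-only update with the slope
#'   fixed at 1 (offset model); the default fits `a` and `b` jointly.
#' @param conf confidence level, default 0.95.
#' @return object of class `cushing_recalibration`: list with elements
#'   `a`, `b` (each estimate, se, ci, p), `b_vs_1` (Wald test of slope
#'   against 1), `interpretation`, and the underlying `glm` fit.
#' @examples
#' set.seed(1)
#' p <- runif(500, 0.05, 0.95)
#' y <- rbinom(500, 1, p)
#' recalibrate(p, y)  # a near 0, b near 1
#' @export
recalibrate <- function(predicted, observed, fix_slope = FALSE, conf = 0.95) {
  v <- validate_cohort_vectors(predicted, observed)
  lp <- logit(clip_probability(v$predicted))
  if (!fix_slope && diff(range(lp)) < .Machine$double.eps^0.5) {
    stop("predicted probabilities are all identical: calibration slope is unidentifiable",
         call. = FALSE)
  }
  if (fix_slope) {
    fit <- glm(v$observed ~ 1 + offset(lp), family = binomial())
    est <- coef(summary(fit))
    a <- .wald(est[1, 1], est[1, 2], conf = conf)
    res <- list(a = c(list(estimate = est[1, 1], se = est[1, 2]), a),
                b = list(estimate = 1, fixed = TRUE), b_vs_1 = NULL)
  } else {
    fit <- glm(v$observed ~ lp, family = binomial())
    est <- coef(summary(fit))
    a <- .wald(est[1, 1], est[1, 2], conf = conf)
    b0 <- .wald(est[2, 1], est[2, 2], null = 0, conf = conf)
    b1 <- .wald(est[2, 1], est[2, 2], null = 1, conf = conf)
    res <- list(a = c(list(estimate = est[1, 1], se = est[1, 2]), a),
                b = c(list(estimate = est[2, 1], se = est[2, 2]), b0),
                b_vs_1 = b1)
  }
  res$interpretation <- if (res$a$estimate < 0) {
    "a < 0: the model overestimates the odds of disease in this cohort"
  } else if (res$a$estimate > 0) {
    "a > 0: the model underestimates the odds of disease in this cohort"
  } else "a = 0: predictions are calibrated in the large"
  res$fit <- fit
  class(res) <- "cushing_recalibration"
  res
}

#' @export
print.cushing_recalibration <- function(x, ...) {
  cat("Logistic recalibration: logit(y) = a + b * logit(yhat)\n")
  cat(sprintf("  calibration-in-the-large a = %.2f (95%% CI %.2f to %.2f), P = %s\n",
              x$a$estimate, x$a$ci[1], x$a$ci[2], format_pvalue(x$a$p)))
  if (isTRUE(x$b$fixed)) {
    cat("  calibration slope fixed at 1 (intercept-only update)\n")
  } else {
    cat(sprintf("  calibration slope        b = %.2f (95%% CI %.2f to %.2f), P(b=0) = %s, P(b=1) = %s\n",
                x$b$estimate, x$b$ci[1], x$b$ci[2],
                format_pvalue(x$b$p), format_pvalue(x$b_vs_1$p)))
  }
  cat(" ", x$interpretation, "\n")
  invisible(x)
}

# rank-based grouping with ties kept in the same bin
.rank_groups <- function(predicted, groups) {
  qs <- quantile(predicted, probs = seq_len(groups - 1) / groups, type = 2)
  g <- findInterval(predicted, unique(qs), left.open = TRUE) + 1L
  as.integer(factor(g))  # renumber contiguously
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Records are ranked by predicted probability and split into near-equal
#' groups (deciles by default, ties kept in the same bin so bins may be
#' unequal). The statistic sums `(O - E)^2 / (E * (1 - mean(yhat)))` over
#' groups, i.e. the squared observed-minus-expected case counts scaled by
#' the binomial variance, and is referred to a chi-square distribution with
#' `groups - 2` degrees of freedom. Groups with zero expected counts are
#' merged with a neighbour with a warning.
#'
#' @inheritParams recalibrate
#' @param groups number of groups (default 10).
#' @return list with `statistic`, `df`, `p`, and the per-group
#'   `table` (n, mean predicted, observed and expected cases).
#' @export
hosmer_lemeshow <- function(predicted, observed, groups = 10) {
  v <- validate_cohort_vectors(predicted, observed, need_both_classes = FALSE)
  if (groups < 3) stop("need at least 3 groups", call. = FALSE)
  if (length(v$observed) < groups) stop("need n >= groups", call. = FALSE)
  g <- .rank_groups(v$predicted, groups)
  split_p <- split(v$predicted, g)
  split_y <- split(v$observed, g)
  tab <- data.frame(
    group = seq_along(split_p),
    n = lengths(split_p),
    mean_predicted = vapply(split_p, mean, numeric(1)),
    observed_cases = vapply(split_y, sum, numeric(1)),
    expected_cases = vapply(split_p, sum, numeric(1))
  )
  # merge degenerate bins (expected 0 cases or 0 non-cases) with a neighbour
  degenerate <- function(t) t$expected_cases <= 0 | (t$n - t$expected_cases) <= 0
  while (any(degenerate(tab)) && nrow(tab) > 3) {
    i <- which(degenerate(tab))[1]
    j <- if (i == 1) 2 else i - 1
    warning("merging Hosmer-Lemeshow bin with zero expected count into its neighbour",
            call. = FALSE)
    tab$n[j] <- tab$n[j] + tab$n[i]
    tab$observed_cases[j] <- tab$observed_cases[j] + tab$observed_cases[i]
    w <- tab$expected_cases[j] + tab$expected_cases[i]
    tab$expected_cases[j] <- w
    tab <- tab[-i, ]
    tab$mean_predicted <- tab$expected_cases / tab$n
  }
  pbar <- tab$expected_cases / tab$n
  statistic <- sum((tab$observed_cases - tab$expected_cases)^2 /
                     (tab$n * pbar * (1 - pbar)))
  df <- nrow(tab) - 2L
  list(statistic = statistic, df = df,
       p = pchisq(statistic, df, lower.tail = FALSE), table = tab)
}

#' Calibration table by groups of predicted probability
#'
#' Mean predicted probability and observed case proportion per group of
#' predictions (deciles by default) - the numbers behind a calibration
#' plot.
#'
#' @inheritParams hosmer_lemeshow
#' @return data frame with one row per group: `n`, `mean_predicted`,
#'   `observed_proportion`, `observed_cases`.
#' @export
calibration_table <- function(predicted, observed, groups = 10) {
  v <- validate_cohort_vectors(predicted, observed, need_both_classes = FALSE)
  g <- .rank_groups(v$predicted, groups)
  data.frame(
    group = sort(unique(g)),
    n = as.vector(table(g)),
    mean_predicted = as.vector(tapply(v$predicted, g, mean)),
    observed_proportion = as.vector(tapply(v$observed, g, mean)),
    observed_cases = as.vector(tapply(v$observed, g, sum))
  )
}

# interpretation bands for the c-statistic; edges: 0.8 and 0.9 are excellent
c_band <- function(c_stat) {
  if (c_stat > 0.9) "outstanding"
  else if (c_stat >= 0.8) "excellent"
  else if (c_stat >= 0.7) "acceptable"
  else "poor"
}

# DeLong variance of the empirical AUC
.delong_se <- function(predicted, observed) {
  x <- predicted[observed == 1]; y <- predicted[observed == 0]
  m <- length(x); n <- length(y)
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  s10 <- if (m > 1) var(v10) else 0
  s01 <- if (n > 1) var(v01) else 0
  sqrt(s10 / m + s01 / n)
}

#' c-statistic (area under the ROC curve) with confidence interval
#'
#' Probability that a randomly chosen case receives a higher predicted
#' probability than a randomly chosen non-case, with ties counted half:
#' `(concordant + 0.5 * tied) / (cases x non-cases)`. Computed via ranks
#' (identical to the pairwise count). The 95% CI uses the DeLong variance
#' by default, or a seeded bootstrap.
#'
#' Bands: 0.5-0.7 poor, 0.7-0.8 acceptable, 0.8-0.9 excellent,
#' above 0.9 outstanding (0.8 and 0.9 both read as excellent).
#'
#' @inheritParams recalibrate
#' @param ci_method `"delong"` (default) or `"bootstrap"`.
#' @param B bootstrap resamples (default 2000).
#' @param seed seed for the bootstrap path.
#' @return object of class `cushing_discrimination`: list with
#'   `c_statistic`, `se`, `ci`, `band`, `n_cases`, `n_noncases`.
#' @export
c_statistic <- function(predicted, observed, ci_method = c("delong", "bootstrap"),
                        conf = 0.95, B = 2000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  v <- validate_cohort_vectors(predicted, observed)
  m <- sum(v$observed == 1); n <- sum(v$observed == 0)
  auc_rank <- function(p, y) {
    r <- rank(p)
    (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
  }
  cstat <- auc_rank(v$predicted, v$observed)
  if (ci_method == "delong") {
    se <- .delong_se(v$predicted, v$observed)
    zq <- qnorm(1 - (1 - conf) / 2)
    ci <- pmin(pmax(cstat + c(-1, 1) * zq * se, 0), 1)
  } else {
    if (!is.null(seed)) set.seed(seed)
    idx1 <- which(v$observed == 1); idx0 <- which(v$observed == 0)
    boots <- replicate(B, {
      i <- c(sample(idx1, m, replace = TRUE), sample(idx0, n, replace = TRUE))
      p <- v$predicted[i]; y <- v$observed[i]
      r <- rank(p)
      (sum(r[y == 1]) - m * (m + 1) / 2) / (m * n)
    })
    se <- sd(boots)
    ci <- unname(quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
  }
  structure(list(c_statistic = cstat, se = se, ci = ci, band = c_band(cstat),
                 ci_method = ci_method, n_cases = m, n_noncases = n),
            class = "cushing_discrimination")
}

#' @export
print.cushing_discrimination <- function(x, ...) {
  cat(sprintf("c-statistic (AUROC) = %.3f (95%% CI %.3f to %.3f, %s): %s discrimination\n",
              x$c_statistic, x$ci[1], x$ci[2], x$ci_method, x$band))
  invisible(x)
}

#' Empirical ROC curve
#'
#' One (1 - specificity, sensitivity) point per distinct predicted value,
#' forming the monotone staircase from (0, 0) to (1, 1). The trapezoidal
#' area under the returned points equals the tie-corrected c-statistic to
#' machine precision.
#'
#' @inheritParams recalibrate
#' @return data frame with columns `threshold` (Inf for the (0,0) corner),
#'   `sensitivity`, `one_minus_specificity`, plus attribute `auc`.
#' @export
roc_curve <- function(predicted, observed) {
  v <- validate_cohort_vectors(predicted, observed)
  m <- sum(v$observed == 1); n <- sum(v$observed == 0)
  thr <- sort(unique(v$predicted), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(v$predicted == t & v$observed == 1), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(v$predicted == t & v$observed == 0), numeric(1)))
  sens <- c(0, tp / m)
  fpr <- c(0, fp / n)
  out <- data.frame(threshold = c(Inf, thr), sensitivity = sens,
                    one_minus_specificity = fpr)
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  attr(out, "auc") <- auc
  out
}

#' Diagnostic performance of the tool at a score threshold
#'
#' Dogs with score at or above the threshold are predicted cases, below it
#' predicted non-cases. Returns the confusion counts and sensitivity,
#' specificity, positive and negative predictive values. Proportions with a
#' zero denominator are returned as `NA` with a warning, not as 0.
#'
#' @param scores integer vector of tool scores.
#' @param observed binary outcome vector (1 = case).
#' @param threshold integer score threshold (predicted positive iff
#'   `score >= threshold`).
#' @return object of class `cushing_thresholds`: list with `threshold`,
#'   `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @examples
#' threshold_diagnostics(c(3, 2, 1, 1, 0), c(1, 1, 1, 0, 0), 2)
#' @export
threshold_diagnostics <- function(scores, observed, threshold) {
  if (is.null(scores) || !length(scores)) {
    stop("tool scores are required for threshold diagnostics", call. = FALSE)
  }
  v <- validate_cohort_vectors(scores, observed, need_both_classes = FALSE)
  pos <- v$predicted >= threshold
  tp <- sum(pos & v$observed == 1); fp <- sum(pos & v$observed == 0)
  fn <- sum(!pos & v$observed == 1); tn <- sum(!pos & v$observed == 0)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  structure(list(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = ratio(tp, tp + fn, "sensitivity"),
                 specificity = ratio(tn, tn + fp, "specificity"),
                 ppv = ratio(tp, tp + fp, "PPV"),
                 npv = ratio(tn, tn + fn, "NPV")),
            class = "cushing_thresholds")
}

#' @export
print.cushing_thresholds <- function(x, ...) {
  cat(sprintf("Score threshold >= %d: TP %d, FP %d, TN %d, FN %d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.0f%%, specificity %.0f%%, PPV %.0f%%, NPV %.0f%%\n",
              100 * x$sensitivity, 100 * x$specificity, 100 * x$ppv, 100 * x$npv))
  invisible(x)
}
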