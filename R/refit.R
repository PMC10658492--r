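# Refitting the model structure in a new cohort: maximum likelihood via
# IRLS, Wald tests, separation detection, and the development-vs-validation
# coefficient comparison.

# thresholds above which a coefficient is flagged as (quasi-)separated:
# diverged estimates print as huge log-odds with enormous standard errors
.SEP_EST <- 10
.SEP_SE <- 100

# build the model design factors with the published baselines
.model_frame <- function(data) {
  data <- resolve_profiles(data)
  data.frame(
    neuter_status = factor(data$neuter_status, levels = NEUTER_LEVELS),
    age = factor(data$age_band3, levels = AGE3_LEVELS),
    breed = factor(data$breed_model, levels = MODEL_BREEDS),
    polydipsia = factor(ifelse(data$polydipsia, "yes", "no"), levels = c("no", "yes")),
    vomiting = factor(ifelse(data$vomiting, "yes", "no"), levels = c("no", "yes")),
    potbelly_hepatomegaly = factor(ifelse(data$potbelly_hepatomegaly, "yes", "no"),
                                   levels = c("no", "yes")),
    alopecia = factor(ifelse(data$alopecia, "yes", "no"), levels = c("no", "yes")),
    pruritus = factor(ifelse(data$pruritus, "yes", "no"), levels = c("no", "yes")),
    usg = factor(data$usg, levels = USG_LEVELS),
    alp = factor(data$alp, levels = ALP_LEVELS)
  )
}

# map glm coefficient names back to (predictor, category) rows
.term_map <- function() {
  rbind(
    data.frame(term = "(Intercept)", predictor = "intercept",
               category = "(intercept)", stringsAsFactors = FALSE),
    data.frame(term = paste0("neuter_status", NEUTER_LEVELS[-1]),
               predictor = "neuter_status", category = NEUTER_LEVELS[-1]),
    data.frame(term = paste0("age", AGE3_LEVELS[-1]),
               predictor = "age", category = AGE3_LEVELS[-1]),
    data.frame(term = paste0("breed", MODEL_BREEDS[-1]),
               predictor = "breed", category = MODEL_BREEDS[-1]),
    data.frame(term = paste0(SIGN_FIELDS, "yes"),
               predictor = SIGN_FIELDS, category = "yes"),
    data.frame(term = paste0("usg", USG_LEVELS[-1]),
               predictor = "usg", category = USG_LEVELS[-1]),
    data.frame(term = paste0("alp", ALP_LEVELS[-1]),
               predictor = "alp", category = ALP_LEVELS[-1])
  )
}

#' Wald test of a coefficient against zero
#'
#' `z = estimate / se`, two-sided p-value from the standard normal.
#'
#' @param estimate,se numeric vectors (se strictly positive).
#' @return list with `z` and `p`.
#' @examples
#' wald_test(-2.16, 0.90)$p  # ~0.016
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0) || any(!is.finite(se))) {
    stop("standard errors must be positive", call. = FALSE)
  }
  z <- estimate / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Refit the prediction model's structure in a cohort
#'
#' Maximum-likelihood logistic regression of the outcome on the ten
#' predictors with the published category structure and baselines
#' (female-entire, age <7, crossbreed, signs absent, USG dilute, ALP
#' elevated). Fitting is iteratively reweighted least squares from zero
#' start values (relative deviance convergence 1e-10, at most 100
#' iterations). Categories that perfectly predict the outcome (complete or
#' quasi-complete separation) yield diverged estimates with inflated
#' standard errors; these are reported as-is and flagged with a warning,
#' mirroring how such rows are conventionally printed.
#'
#' @param data cohort data frame including an outcome column.
#' @param outcome name of the binary outcome column (1/`"case"` = case).
#' @param start optional named numeric vector of starting coefficients
#'   (default all zeros); fitting is deterministic either way.
#' @return object of class `cushing_refit`: list with `coefficients` (a
#'   `cushing_coefficients`-style data frame plus `z` and `p` columns),
#'   `converged`, `separation` (flagged term labels), `loglik`, `n`, and
#'   the underlying `glm` fit.
#' @export
fit_logistic <- function(data, outcome = "outcome", start = NULL) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  y <- data[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "case")
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop("outcome must be binary (0/1 or case/noncase)", call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both outcome classes must be present to refit the model", call. = FALSE)
  }
  mf <- .model_frame(data)
  if (nrow(mf) < ncol(stats::model.matrix(~ ., mf))) {
    stop("fewer records than model parameters", call. = FALSE)
  }
  X <- stats::model.matrix(~ ., mf)
  start_vec <- rep(0, ncol(X))
  if (!is.null(start)) {
    idx <- match(names(start), colnames(X))
    start_vec[idx[!is.na(idx)]] <- start[!is.na(idx)]
  }
  fit <- suppressWarnings(glm.fit(X, y, family = binomial(),
                                  start = start_vec,
                                  control = glm.control(epsilon = 1e-10, maxit = 100)))
  est <- fit$coefficients
  # dispersion-free covariance from the final IRLS weights
  W <- fit$weights
  XtWX <- crossprod(X * sqrt(W))
  cov <- tryCatch(solve(XtWX), error = function(e) {
    MASS_ginv <- function(M) { s <- svd(M); keep <- s$d > max(s$d) * 1e-12
      s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep]) }
    MASS_ginv(XtWX)
  })
  se <- sqrt(pmax(diag(cov), 0))
  separated <- names(est)[which(abs(est) > .SEP_EST | se > .SEP_SE)]
  if (length(separated)) {
    warning("possible separation: diverged estimate(s) for ",
            paste(separated, collapse = ", "), call. = FALSE)
  }
  map <- .term_map()
  idx <- match(map$term, names(est))
  coefs <- data.frame(predictor = map$predictor, category = map$category,
                      estimate = unname(est[idx]), se = unname(se[idx]),
                      stringsAsFactors = FALSE)
  # add the baseline rows (coefficient exactly 0) so the table mirrors the
  # published structure and lines up with cushing_coefficients()
  skeleton <- cushing_coefficients("development")[, c("predictor", "category")]
  coefs <- merge(skeleton, coefs, by = c("predictor", "category"),
                 all.x = TRUE, sort = FALSE)
  baseline <- !(paste(coefs$predictor, coefs$category) %in%
                  paste(map$predictor, map$category))
  coefs$estimate[baseline] <- 0
  coefs <- coefs[match(paste(skeleton$predictor, skeleton$category),
                       paste(coefs$predictor, coefs$category)), ]
  rownames(coefs) <- NULL
  # missing design columns (e.g. a breed absent from the cohort) stay NA
  ok <- !is.na(coefs$estimate) & !is.na(coefs$se) & coefs$se > 0
  coefs$z <- coefs$p <- NA_real_
  wt <- wald_test(coefs$estimate[ok], coefs$se[ok])
  coefs$z[ok] <- wt$z
  coefs$p[ok] <- wt$p
  loglik <- sum(y * log(fit$fitted.values) + (1 - y) * log(1 - fit$fitted.values))
  structure(list(coefficients = coefs, converged = fit$converged,
                 separation = separated, loglik = loglik, n = length(y),
                 fit = fit),
            class = "cushing_refit")
}

#' @export
print.cushing_refit <- function(x, ...) {
  cat(sprintf("Refitted Cushing's model: n = %d, log-likelihood = %.2f, converged: %s\n",
              x$n, x$loglik, x$converged))
  if (length(x$separation)) {
    cat("  separation flagged for:", paste(x$separation, collapse = ", "), "\n")
  }
  df <- x$coefficients
  df$p <- format_pvalue(df$p)
  print(df, digits = 3)
  invisible(x)
}

#' Compare development and refitted coefficients side by side
#'
#' Pairs each predictor category's development-cohort coefficient and SE
#' with its refitted counterpart, the refit Wald p-value, and a labelled
#' supplementary heterogeneity statistic
#' `z = (r_val - r_dev) / sqrt(SE_dev^2 + SE_val^2)` quantifying the
#' difference in predictor-outcome association between cohorts.
#'
#' @param dev coefficient table (e.g. `cushing_coefficients("development")`).
#' @param val a `cushing_refit` object, or a coefficient table with the
#'   same structure (e.g. `cushing_coefficients("validation")`).
#' @return data frame with columns `predictor`, `category`, `r_dev`,
#'   `se_dev`, `r_val`, `se_val`, `p_val`, `heterogeneity_z`.
#' @export
compare_coefficients <- function(dev = cushing_coefficients("development"), val) {
  vtab <- if (inherits(val, "cushing_refit")) val$coefficients else val
  stopifnot(is.data.frame(dev), is.data.frame(vtab))
  if (!"p" %in% names(vtab)) {
    vtab$p <- NA_real_
    ok <- !is.na(vtab$estimate) & !is.na(vtab$se) & vtab$se > 0
    vtab$p[ok] <- wald_test(vtab$estimate[ok], vtab$se[ok])$p
  }
  key_d <- paste(dev$predictor, dev$category)
  key_v <- paste(vtab$predictor, vtab$category)
  if (!setequal(key_d, key_v)) {
    stop("coefficient structures differ; unmatched categories: ",
         paste(c(setdiff(key_d, key_v), setdiff(key_v, key_d)), collapse = ", "),
         call. = FALSE)
  }
  vtab <- vtab[match(key_d, key_v), ]
  out <- data.frame(predictor = dev$predictor, category = dev$category,
                    r_dev = dev$estimate, se_dev = dev$se,
                    r_val = vtab$estimate, se_val = vtab$se,
                    p_val = vtab$p, stringsAsFactors = FALSE)
  both <- !is.na(out$se_dev) & !is.na(out$se_val)
  out$heterogeneity_z <- NA_real_
  out$heterogeneity_z[both] <- (out$r_val[both] - out$r_dev[both]) /
    sqrt(out$se_dev[both]^2 + out$se_val[both]^2)
  out
}
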