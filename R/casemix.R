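# Case-mix / transportability machinery: exact contingency-table tests,
# rank-sum comparison, stratified baseline tables, and cohort-vs-cohort
# comparison from summary percentages.

# relative tolerance for "at most as probable as observed" ties, keeping
# enumeration results platform-stable
.FISHER_TOL <- 1e-7

validate_table <- function(tab) {
  if (!is.matrix(tab) || !is.numeric(tab)) {
    stop("contingency table must be a numeric matrix", call. = FALSE)
  }
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("contingency table counts must be non-negative integers", call. = FALSE)
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("contingency table needs at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table margins must all be positive", call. = FALSE)
  }
  storage.mode(tab) <- "double"
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test of association. The p-value is the sum of
#' hypergeometric probabilities of all tables with the observed margins
#' whose point probability does not exceed that of the observed table
#' (point-probability convention, with a relative tie tolerance of 1e-7).
#'
#' @param tab 2x2 non-negative integer matrix with positive margins.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(matrix(c(3, 77, 20, 130), 2, byrow = TRUE))  # ~0.021
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- validate_table(tab)
  if (nrow(tab) != 2 || ncol(tab) != 2) {
    stop("table is not 2x2; use fisher_exact_rxc()", call. = FALSE)
  }
  m <- sum(tab[, 1]); n <- sum(tab[, 2]); k <- sum(tab[1, ])
  support <- max(0, k - n):min(k, m)
  d <- dhyper(support, m, n, k)
  d_obs <- dhyper(tab[1, 1], m, n, k)
  min(1, sum(d[d <= d_obs * (1 + .FISHER_TOL)]))
}

# log point probability of a table under the fixed-margins null
.log_table_prob <- function(tab) {
  sum(lgamma(rowSums(tab) + 1)) + sum(lgamma(colSums(tab) + 1)) -
    lgamma(sum(tab) + 1) - sum(lgamma(tab + 1))
}

# enumerate all r x c tables with the given margins, calling fun(tab) on each;
# rows are filled cell by cell, with each row's last cell and the whole last
# row determined by the margins
.enumerate_tables <- function(row_margins, col_margins, fun) {
  r <- length(row_margins); cc <- length(col_margins)
  cells <- matrix(0, r, cc)
  fill <- function(i, j, row_left, col_left) {
    if (i == r) {
      cells[r, ] <<- col_left
      fun(cells)
      return(invisible())
    }
    if (j == cc) {
      if (row_left > col_left[cc]) return(invisible())
      cells[i, cc] <<- row_left
      cl <- col_left; cl[cc] <- cl[cc] - row_left
      fill(i + 1, 1, row_margins[i + 1], cl)
      return(invisible())
    }
    for (x in 0:min(row_left, col_left[j])) {
      cells[i, j] <<- x
      cl <- col_left; cl[j] <- cl[j] - x
      fill(i, j + 1, row_left - x, cl)
    }
    invisible()
  }
  fill(1, 1, row_margins[1], col_margins)
  invisible()
}

#' Fisher's exact test for an r x c table (Freeman-Halton extension)
#'
#' Exhaustive enumeration over all tables with the observed margins; the
#' p-value sums the probabilities of tables at most as probable as the
#' observed one (relative tie tolerance 1e-7). Enumeration is guarded by
#' the table total; beyond the guard a seeded Monte Carlo estimate over
#' random tables with the observed margins is available.
#'
#' @param tab r x c non-negative integer matrix with positive margins.
#'   2x2 input is routed to [fisher_exact_2x2()].
#' @param max_total largest table total for exhaustive enumeration
#'   (default 500).
#' @param simulate if `TRUE`, estimate the p-value by Monte Carlo instead
#'   of enumerating (required when the guard is exceeded).
#' @param B number of Monte Carlo tables (default 1e5).
#' @param seed RNG seed for the Monte Carlo path.
#' @return two-sided p-value in (0, 1].
#' @examples
#' neuter <- matrix(c(9, 29, 22, 20, 17, 78, 16, 39), 2, byrow = TRUE)
#' fisher_exact_rxc(neuter)  # ~0.0096
#' @export
fisher_exact_rxc <- function(tab, max_total = 500, simulate = FALSE,
                             B = 1e5, seed = NULL) {
  tab <- validate_table(tab)
  if (nrow(tab) == 2 && ncol(tab) == 2) return(fisher_exact_2x2(tab))
  logp_obs <- .log_table_prob(tab)
  cut <- logp_obs + log1p(.FISHER_TOL)
  if (simulate) {
    if (!is.null(seed)) set.seed(seed)
    sims <- r2dtable(B, rowSums(tab), colSums(tab))
    hits <- vapply(sims, function(s) .log_table_prob(s) <= cut, logical(1))
    return((1 + sum(hits)) / (B + 1))
  }
  if (sum(tab) > max_total) {
    stop("table total exceeds the enumeration guard (", max_total,
         "); re-run with simulate = TRUE for a seeded Monte Carlo p-value",
         call. = FALSE)
  }
  acc <- 0
  .enumerate_tables(rowSums(tab), colSums(tab), function(tt) {
    lp <- .log_table_prob(tt)
    if (lp <= cut) acc <<- acc + exp(lp)
  })
  min(1, acc)
}

#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided test; exact distribution when the smaller sample has at most
#' 25 observations and there are no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param x,y numeric vectors, each non-empty.
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 25 && !ties
  suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
  )
}

# pick the right association test for a stratified categorical variable
.categorical_p <- function(counts) {
  tab <- t(counts)  # categories x strata -> strata x categories
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  if (nrow(tab) < 2 || ncol(tab) < 2) return(NA_real_)
  if (ncol(tab) == 2 && nrow(tab) == 2) return(fisher_exact_2x2(tab))
  if (sum(tab) <= 500) return(fisher_exact_rxc(tab))
  fisher_exact_rxc(tab, simulate = TRUE, seed = 1L)
}

#' Baseline-characteristics table stratified by outcome
#'
#' Builds the standard per-variable summary comparing cases and non-cases:
#' counts and percentages per stratum for categorical variables with a
#' Fisher's exact p-value (2x2 or exact r x c), and median (range) per
#' stratum for numeric variables with a Wilcoxon rank-sum p-value. Values
#' recorded as `"not_recorded"` form their own category.
#'
#' @param data cohort data frame.
#' @param variables character vector of column names to summarise.
#' @param stratifier name of a binary column (e.g. `outcome` with values
#'   0/1 or `"case"`/`"noncase"`).
#' @return data frame with one row per variable/category: counts,
#'   percentages (1 decimal) per stratum, the test used and its p-value.
#' @export
baseline_table <- function(data, variables, stratifier = "outcome") {
  stopifnot(is.data.frame(data), stratifier %in% names(data))
  strata <- as.factor(data[[stratifier]])
  if (nlevels(strata) != 2) stop("stratifier must be binary", call. = FALSE)
  rows <- list()
  for (v in variables) {
    if (!v %in% names(data)) {
      warning("variable not in cohort, skipped: ", v, call. = FALSE)
      next
    }
    x <- data[[v]]
    if (is.numeric(x) && length(unique(x)) > 2) {
      p <- tryCatch(wilcoxon_rank_sum(x[strata == levels(strata)[1]],
                                      x[strata == levels(strata)[2]]),
                    error = function(e) NA_real_)
      med <- tapply(x, strata, function(z)
        sprintf("%.1f (%.1f-%.1f)", median(z), min(z), max(z)))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, category = "median (range)",
        stratum1 = med[1], stratum2 = med[2],
        test = "wilcoxon_rank_sum", p = p, stringsAsFactors = FALSE)
    } else {
      if (is.logical(x)) x <- ifelse(x, "yes", "no")
      x <- as.factor(x)
      counts <- table(x, strata)
      p <- tryCatch(.categorical_p(counts), error = function(e) NA_real_)
      tot <- colSums(counts)
      for (lev in rownames(counts)) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, category = lev,
          stratum1 = sprintf("%d (%.1f)", counts[lev, 1],
                             100 * counts[lev, 1] / tot[1]),
          stratum2 = sprintf("%d (%.1f)", counts[lev, 2],
                             100 * counts[lev, 2] / tot[2]),
          test = "fisher_exact",
          p = ifelse(lev == rownames(counts)[1], p, NA_real_),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  names(out)[3:4] <- paste0(levels(strata), c("", ""))
  rownames(out) <- NULL
  out
}

#' Compare two cohort summaries category by category
#'
#' For each category shared by two cohort summaries, builds the 2x2 table
#' of in-category vs not-in-category by cohort and computes Fisher's exact
#' p-value. Summaries may give counts or percentages; percentages are
#' converted to counts by rounding `percent x total / 100` to the nearest
#' integer and such rows are flagged as reconstructed.
#'
#' @param summary_a,summary_b data frames with columns `variable`,
#'   `category` and either `count` or `percent`.
#' @param n_a,n_b cohort totals.
#' @return data frame with per-category counts in both cohorts,
#'   percentages, the exact p-value (missing where a category is absent
#'   from one summary) and a `reconstructed` flag.
#' @examples
#' a <- data.frame(variable = "outcome", category = "case", percent = 42.4)
#' b <- data.frame(variable = "outcome", category = "case", percent = 34.8)
#' cohort_compare(a, b, n_a = 939, n_b = 230)  # p ~0.036
#' @export
cohort_compare <- function(summary_a, summary_b, n_a, n_b) {
  get_counts <- function(s, n) {
    stopifnot(all(c("variable", "category") %in% names(s)))
    if ("count" %in% names(s) && any(!is.na(s$count))) {
      data.frame(variable = s$variable, category = s$category,
                 count = as.integer(s$count), reconstructed = FALSE,
                 stringsAsFactors = FALSE)
    } else if ("percent" %in% names(s)) {
      data.frame(variable = s$variable, category = s$category,
                 count = as.integer(round(s$percent * n / 100)),
                 reconstructed = TRUE, stringsAsFactors = FALSE)
    } else {
      stop("summary needs a count or percent column", call. = FALSE)
    }
  }
  a <- get_counts(summary_a, n_a)
  b <- get_counts(summary_b, n_b)
  keys <- merge(a, b, by = c("variable", "category"), all = TRUE,
                suffixes = c("_a", "_b"))
  keys$percent_a <- round(100 * keys$count_a / n_a, 1)
  keys$percent_b <- round(100 * keys$count_b / n_b, 1)
  keys$p <- NA_real_
  for (i in seq_len(nrow(keys))) {
    ca <- keys$count_a[i]; cb <- keys$count_b[i]
    if (is.na(ca) || is.na(cb)) next
    tab <- matrix(c(ca, n_a - ca, cb, n_b - cb), 2, byrow = TRUE)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    keys$p[i] <- fisher_exact_2x2(tab)
  }
  keys$reconstructed <- keys$reconstructed_a | keys$reconstructed_b
  keys[, c("variable", "category", "count_a", "percent_a",
           "count_b", "percent_b", "p", "reconstructed")]
}
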