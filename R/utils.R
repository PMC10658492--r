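# shared numerical helpers

#' Clip probabilities away from 0 and 1
#'
#' The published score lookup includes endpoints of 0% and 96%; a predicted
#' probability of exactly 0 or 1 has an infinite logit, which would break the
#' recalibration model. All probabilities entering a logit transform are
#' therefore clipped into `[floor, ceiling]` first.
#'
#' @param p numeric vector of probabilities.
#' @param floor,ceiling clipping bounds, defaults 0.001 and 0.999.
#' @return numeric vector with values forced into `[floor, ceiling]`.
#' @export
clip_probability <- function(p, floor = 0.001, ceiling = 0.999) {
  stopifnot(is.numeric(p), floor > 0, ceiling < 1, floor < ceiling)
  pmin(pmax(p, floor), ceiling)
}

# logit / inverse logit, kept as thin aliases for readability
logit <- function(p) qlogis(p)
expit <- function(x) plogis(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent error for bad categorical values, naming the offending field
check_category <- function(x, allowed, field) {
  x <- as.character(x)
  bad <- !(x %in% allowed)
  if (any(bad)) {
    stop(sprintf("unknown %s value(s): %s (allowed: %s)", field,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(allowed, collapse = ", ")), call. = FALSE)
  }
  x
}

# format a p-value the way veterinary clinical journals print them
#' Format a p-value for reporting
#'
#' Three decimals, with values below 0.001 printed as "<.001".
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<.001", sub("^0", "", sprintf("%.3f", p))))
}
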