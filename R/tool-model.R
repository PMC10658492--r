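# The prediction tool itself: profile normalisation, the points score, the
# full logistic model, and the score -> likelihood lookup.

#' Normalise a breed label to a tool category
#'
#' Breed labels are matched case-insensitively after stripping punctuation,
#' against a synonym list covering common spellings and abbreviations. The
#' points score and the full model use different breed baselines: the score
#' pools crossbreeds with unlisted purebreds into `"other"`, whereas the
#' model distinguishes `"crossbreed"` (its baseline) from
#' `"other_purebred"` and recognises four additional breeds.
#'
#' @param breed character vector of free-text breed labels.
#' @param scheme `"score"` (six categories of the points grid) or
#'   `"model"` (ten categories of the regression model).
#' @return character vector of canonical breed categories.
#' @examples
#' normalise_breed("West Highland White Terrier")           # score category
#' normalise_breed("Jack Russell terrier", scheme = "model")
#' @export
normalise_breed <- function(breed, scheme = c("score", "model")) {
  scheme <- match.arg(scheme)
  key <- tolower(as.character(breed))
  key <- gsub("[^a-z0-9]+", " ", key)
  key <- trimws(gsub(" +", " ", key))
  synonyms <- c(
    "bichon frise" = "bichon_frise", "bichon" = "bichon_frise",
    "border terrier" = "border_terrier",
    "labrador retriever" = "labrador_retriever", "labrador" = "labrador_retriever",
    "schnauzer" = "schnauzer", "miniature schnauzer" = "schnauzer",
    "giant schnauzer" = "schnauzer", "standard schnauzer" = "schnauzer",
    "west highland white terrier" = "west_highland_white_terrier",
    "westie" = "west_highland_white_terrier",
    "whwt" = "west_highland_white_terrier",
    "jack russell terrier" = "jack_russell_terrier",
    "jack russel terrier" = "jack_russell_terrier",
    "jrt" = "jack_russell_terrier",
    "staffordshire bull terrier" = "staffordshire_bull_terrier",
    "staffie" = "staffordshire_bull_terrier",
    "staffy" = "staffordshire_bull_terrier",
    "yorkshire terrier" = "yorkshire_terrier", "yorkie" = "yorkshire_terrier",
    "crossbreed" = "crossbreed", "cross breed" = "crossbreed",
    "cross" = "crossbreed", "mixed" = "crossbreed",
    "mixed breed" = "crossbreed", "mongrel" = "crossbreed", "x" = "crossbreed",
    # allow already-canonical tokens through
    "bichon_frise" = "bichon_frise", "border_terrier" = "border_terrier",
    "labrador_retriever" = "labrador_retriever",
    "west_highland_white_terrier" = "west_highland_white_terrier",
    "jack_russell_terrier" = "jack_russell_terrier",
    "staffordshire_bull_terrier" = "staffordshire_bull_terrier",
    "yorkshire_terrier" = "yorkshire_terrier",
    "other_purebred" = "other_purebred", "other purebred" = "other_purebred",
    "other purebreed" = "other_purebred", "other" = "other_purebred"
  )
  canon <- unname(synonyms[gsub("[^a-z0-9]+", " ", key)])
  canon[is.na(canon)] <- "other_purebred"
  if (scheme == "score") {
    canon[!(canon %in% SCORE_BREEDS)] <- "other"
    canon
  } else {
    canon
  }
}

# age -> band used by the points grid
age_band2 <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years >= 0 | is.na(age_years)))
  ifelse(age_years < 7, "<7", ">=7")
}

# age -> band used by the regression model (left-closed edges: 7 -> middle band)
age_band3 <- function(age_years) {
  stopifnot(is.numeric(age_years), all(age_years >= 0 | is.na(age_years)))
  ifelse(age_years < 7, "<7", ifelse(age_years < 11, "7_to_<11", ">=11"))
}

#' Build a single-dog predictor profile
#'
#' Convenience constructor for a one-row cohort data frame holding the ten
#' tool predictors. Clinical signs not supplied are considered absent (the
#' scoring convention for signs missing from a medical record); laboratory
#' categories not supplied default to their explicit `"not_recorded"`
#' category, never to absent.
#'
#' @param neuter_status one of `"female_entire"`, `"female_neutered"`,
#'   `"male_entire"`, `"male_neutered"`.
#' @param age_years non-negative age in years.
#' @param breed free-text breed label (see [normalise_breed()]).
#' @param polydipsia,vomiting,potbelly_hepatomegaly,alopecia,pruritus
#'   logical presence flags; default `FALSE` (absent).
#' @param usg urine specific gravity category: `"dilute"` (<= 1.020),
#'   `"not_dilute"` (> 1.020) or `"not_recorded"`.
#' @param alp serum alkaline phosphatase category: `"elevated"`,
#'   `"not_elevated"` or `"not_recorded"`.
#' @return one-row data frame usable with [score_cohort()],
#'   [linear_predictor()] and [predict_probability()].
#' @examples
#' dog <- predictor_profile("male_neutered", 9, "labrador",
#'                          polydipsia = TRUE, potbelly_hepatomegaly = TRUE)
#' score_cohort(dog)$total
#' @export
predictor_profile <- function(neuter_status, age_years, breed,
                              polydipsia = FALSE, vomiting = FALSE,
                              potbelly_hepatomegaly = FALSE,
                              alopecia = FALSE, pruritus = FALSE,
                              usg = "not_recorded", alp = "not_recorded") {
  data.frame(
    neuter_status = check_category(neuter_status, NEUTER_LEVELS, "neuter_status"),
    age_years = age_years, breed = as.character(breed),
    polydipsia = isTRUE(polydipsia), vomiting = isTRUE(vomiting),
    potbelly_hepatomegaly = isTRUE(potbelly_hepatomegaly),
    alopecia = isTRUE(alopecia), pruritus = isTRUE(pruritus),
    usg = check_category(usg, USG_LEVELS, "usg"),
    alp = check_category(alp, ALP_LEVELS, "alp"),
    stringsAsFactors = FALSE
  )
}

# validate and normalise the predictor columns of a cohort data frame;
# returns the data frame with canonical types plus derived breed/age bands
resolve_profiles <- function(data) {
  stopifnot(is.data.frame(data))
  required <- c("neuter_status", "age_years", "breed")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data
  out$neuter_status <- check_category(out$neuter_status, NEUTER_LEVELS, "neuter_status")
  if (!is.numeric(out$age_years) || any(is.na(out$age_years)) ||
      any(out$age_years < 0)) {
    stop("age_years must be non-negative and numeric for every record",
         call. = FALSE)
  }
  for (sign in SIGN_FIELDS) {
    if (!sign %in% names(out)) {
      out[[sign]] <- FALSE  # sign not mentioned -> considered absent
    } else {
      v <- out[[sign]]
      if (is.character(v) || is.factor(v)) {
        v <- as.character(v)
        v[is.na(v) | v == ""] <- "no"
        v <- check_category(v, c("yes", "no"), sign) == "yes"
      } else {
        v <- as.logical(v)
        v[is.na(v)] <- FALSE
      }
      out[[sign]] <- v
    }
  }
  if (!"usg" %in% names(out)) out$usg <- "not_recorded"
  if (!"alp" %in% names(out)) out$alp <- "not_recorded"
  out$usg[is.na(out$usg) | out$usg == ""] <- "not_recorded"
  out$alp[is.na(out$alp) | out$alp == ""] <- "not_recorded"
  out$usg <- check_category(out$usg, USG_LEVELS, "usg")
  out$alp <- check_category(out$alp, ALP_LEVELS, "alp")
  out$breed_score <- normalise_breed(out$breed, "score")
  out$breed_model <- normalise_breed(out$breed, "model")
  out$age_band2 <- age_band2(out$age_years)
  out$age_band3 <- age_band3(out$age_years)
  out
}

#' Score a cohort with the points-based prediction tool
#'
#' Adds together the points corresponding to each dog's category on the ten
#' predictors. The achievable total spans -13 to 10.
#'
#' @param data cohort data frame (see [predictor_profile()] and
#'   [read_cohort()] for the expected columns).
#' @param grid points grid, default [cushing_points_grid()].
#' @return data frame of per-predictor integer contributions with a final
#'   `total` column, one row per dog.
#' @export
score_cohort <- function(data, grid = cushing_points_grid()) {
  data <- resolve_profiles(data)
  n <- nrow(data)
  contrib <- data.frame(row.names = seq_len(n))
  contrib$neuter_status <- unname(grid$neuter_status[data$neuter_status])
  contrib$age <- unname(grid$age[data$age_band2])
  contrib$breed <- unname(grid$breed[data$breed_score])
  for (sign in SIGN_FIELDS) {
    contrib[[sign]] <- unname(grid[[sign]][ifelse(data[[sign]], "yes", "no")])
  }
  contrib$usg <- unname(grid$usg[data$usg])
  contrib$alp <- unname(grid$alp[data$alp])
  contrib$total <- as.integer(rowSums(contrib))
  contrib
}

#' Achievable score range of a points grid
#'
#' Exhaustively enumerates one category per predictor and returns the
#' minimum and maximum achievable total. For the published grid this is
#' exactly `c(-13, 10)`.
#'
#' @param grid points grid, default [cushing_points_grid()].
#' @return integer vector `c(min, max)`.
#' @export
score_range <- function(grid = cushing_points_grid()) {
  combos <- expand.grid(lapply(unclass(grid), unname))
  totals <- rowSums(combos)
  c(as.integer(min(totals)), as.integer(max(totals)))
}

# turn a cohort into the model's category labels per predictor, as a list of
# character vectors aligned with the coefficient table
model_categories <- function(data) {
  list(neuter_status = data$neuter_status,
       age = data$age_band3,
       breed = data$breed_model,
       polydipsia = ifelse(data$polydipsia, "yes", "no"),
       vomiting = ifelse(data$vomiting, "yes", "no"),
       potbelly_hepatomegaly = ifelse(data$potbelly_hepatomegaly, "yes", "no"),
       alopecia = ifelse(data$alopecia, "yes", "no"),
       pruritus = ifelse(data$pruritus, "yes", "no"),
       usg = data$usg,
       alp = data$alp)
}

#' Linear predictor of the full logistic model
#'
#' Intercept plus the sum of the matching category coefficients (baseline
#' categories contribute 0) for each dog.
#'
#' @param data cohort data frame.
#' @param coefs coefficient table, default the development-cohort
#'   coefficients [cushing_coefficients()].
#' @return numeric vector of log-odds, one per dog.
#' @examples
#' linear_predictor(predictor_profile("female_entire", 5, "crossbreed",
#'                                    usg = "dilute", alp = "elevated"))
#' @export
linear_predictor <- function(data, coefs = cushing_coefficients("development")) {
  data <- resolve_profiles(data)
  stopifnot(inherits(coefs, "cushing_coefficients") || is.data.frame(coefs))
  lp <- rep(coefs$estimate[coefs$predictor == "intercept"], nrow(data))
  cats <- model_categories(data)
  for (pred in names(cats)) {
    rows <- coefs$predictor == pred
    if (pred %in% SIGN_FIELDS) {
      # sign predictors carry a single "yes" coefficient; "no" is baseline
      beta <- c(setNames(coefs$estimate[rows & coefs$category == "yes"], "yes"),
                no = 0)
    } else {
      beta <- setNames(coefs$estimate[rows], coefs$category[rows])
    }
    unmatched <- setdiff(unique(cats[[pred]]), names(beta))
    if (length(unmatched)) {
      stop(sprintf("category not mappable to coefficient set for %s: %s",
                   pred, paste(unmatched, collapse = ", ")), call. = FALSE)
    }
    lp <- lp + unname(beta[cats[[pred]]])
  }
  lp
}

#' Predicted probability of Cushing's syndrome from the full model
#'
#' Inverse-logit of the linear predictor.
#'
#' @inheritParams linear_predictor
#' @return numeric vector of probabilities in (0, 1), with attribute
#'   `source = "full_model"`.
#' @export
predict_probability <- function(data, coefs = cushing_coefficients("development")) {
  p <- plogis(linear_predictor(data, coefs))
  attr(p, "source") <- "full_model"
  p
}

#' Map tool scores to predicted likelihoods via a lookup table
#'
#' The original publication pairs each total score with a predicted
#' likelihood (0% at score -13 up to 96% at score 10); only the endpoints
#' are restated with the grid, so the lookup must be supplied by the user.
#' Looked-up probabilities are clipped into `[floor, ceiling]` so that
#' downstream logit transforms stay finite.
#'
#' @param score integer vector of tool scores in `[-13, 10]`.
#' @param lookup data frame with columns `score` and `probability`,
#'   covering every queried score, with probability monotone non-decreasing
#'   in score.
#' @param floor,ceiling clipping bounds applied after lookup.
#' @return numeric vector of probabilities with attribute
#'   `source = "score_lookup"`.
#' @export
score_to_probability <- function(score, lookup, floor = 0.001, ceiling = 0.999) {
  stopifnot(is.data.frame(lookup), all(c("score", "probability") %in% names(lookup)))
  lookup <- lookup[order(lookup$score), ]
  if (is.unsorted(lookup$probability)) {
    stop("lookup probabilities must be monotone non-decreasing in score",
         call. = FALSE)
  }
  if (any(score < -13 | score > 10)) {
    stop("score outside the achievable range [-13, 10]", call. = FALSE)
  }
  idx <- match(score, lookup$score)
  if (any(is.na(idx))) {
    stop("lookup does not cover score(s): ",
         paste(unique(score[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  p <- clip_probability(lookup$probability[idx], floor, ceiling)
  attr(p, "source") <- "score_lookup"
  p
}
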