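# Published constants: the scoring grid, the development and
# external-validation regression coefficients, the non-case final-diagnosis
# breakdown, and the contingency tables reported alongside the tool.

# canonical category levels used throughout the package
NEUTER_LEVELS <- c("female_entire", "female_neutered", "male_entire", "male_neutered")
SIGN_FIELDS   <- c("polydipsia", "vomiting", "potbelly_hepatomegaly", "alopecia", "pruritus")
USG_LEVELS    <- c("dilute", "not_dilute", "not_recorded")
ALP_LEVELS    <- c("elevated", "not_elevated", "not_recorded")
AGE3_LEVELS   <- c("<7", "7_to_<11", ">=11")

# breed categories of the full regression model (crossbreed is baseline)
MODEL_BREEDS <- c("crossbreed", "bichon_frise", "border_terrier",
                  "jack_russell_terrier", "labrador_retriever",
                  "other_purebred", "schnauzer", "staffordshire_bull_terrier",
                  "west_highland_white_terrier", "yorkshire_terrier")
# breed categories of the points score (everything else scores as other)
SCORE_BREEDS <- c("bichon_frise", "border_terrier", "labrador_retriever",
                  "schnauzer", "west_highland_white_terrier", "other")

#' The published points grid of the Cushing's prediction tool
#'
#' Integer points per predictor category. Summing one category per predictor
#' yields the tool score; the achievable total spans -13 to 10. The age
#' threshold for the score is 7 years (`<7` scores 0, `>=7` scores 1).
#'
#' @return an object of class `cushing_points_grid`: a named list of named
#'   integer vectors, one per predictor.
#' @examples
#' grid <- cushing_points_grid()
#' grid$potbelly_hepatomegaly["yes"]  # +3
#' @export
cushing_points_grid <- function() {
  grid <- list(
    neuter_status = c(female_entire = 0L, female_neutered = -1L,
                      male_entire = -1L, male_neutered = -1L),
    age = c("<7" = 0L, ">=7" = 1L),
    breed = c(bichon_frise = 2L, border_terrier = 1L,
              labrador_retriever = -3L, schnauzer = -2L,
              west_highland_white_terrier = -3L, other = 0L),
    polydipsia = c(yes = 2L, no = 0L),
    vomiting = c(yes = -2L, no = 0L),
    potbelly_hepatomegaly = c(yes = 3L, no = 0L),
    alopecia = c(yes = 2L, no = 0L),
    pruritus = c(yes = -2L, no = 0L),
    usg = c(dilute = 0L, not_dilute = -2L, not_recorded = -1L),
    alp = c(elevated = 0L, not_elevated = -3L, not_recorded = 0L)
  )
  structure(grid, class = "cushing_points_grid", age_threshold = 7)
}

# helper for building coefficient tables
.coef_row <- function(predictor, category, estimate, se) {
  data.frame(predictor = predictor, category = category,
             estimate = estimate, se = se, stringsAsFactors = FALSE)
}

#' Published regression coefficients of the Cushing's prediction model
#'
#' Log-odds coefficients and standard errors of the full logistic model, as
#' estimated in the UK primary-care development cohort (`"development"`,
#' cases n = 398, non-cases n = 541) and as refitted in the Dutch
#' secondary-care external-validation cohort (`"validation"`, cases n = 80,
#' non-cases n = 150). Baseline categories (female-entire; age <7;
#' crossbreed; each sign absent; USG dilute; ALP elevated) carry coefficient
#' exactly 0 and are included as explicit rows with `se = NA`.
#'
#' Age is banded as `<7`, `7_to_<11`, `>=11` (band edges closed on the
#' left, so an age of exactly 7 falls in the middle band).
#'
#' @param set `"development"` or `"validation"`.
#' @return an object of class `cushing_coefficients`: a data frame with
#'   columns `predictor`, `category`, `estimate`, `se`.
#' @examples
#' dev <- cushing_coefficients("development")
#' dev[dev$predictor == "intercept", ]  # -0.49 (SE 0.38)
#' @export
cushing_coefficients <- function(set = c("development", "validation")) {
  set <- match.arg(set)
  est_dev <- c(-0.49,
               0, -0.64, -0.34, -0.60,
               0, 0.64, 0.58,
               0, 0.68, 0.61, 0.11, -1.37, -0.04, -1.03, 0.05, -1.18, 0.09,
               0.87, -0.76, 1.11, 0.94, -0.88,
               0, -0.85, -0.43,
               0, -1.46, -0.16)
  se_dev <- c(0.38,
              NA, 0.27, 0.32, 0.27,
              NA, 0.26, 0.27,
              NA, 0.34, 0.44, 0.30, 0.49, 0.20, 0.53, 0.35, 0.37, 0.40,
              0.16, 0.31, 0.17, 0.20, 0.35,
              NA, 0.26, 0.20,
              NA, 0.35, 0.16)
  est_val <- c(-1.31,
               0, -0.20, 1.44, 0.04,
               0, 0.47, 0.05,
               0, 15.81, -19.45, 0.81, -0.97, -0.12, -14.67, -11.97, -16.54, -1.15,
               1.16, -2.16, 0.74, 2.49, -1.85,
               0, -2.02, -1.61,
               0, -2.96, -0.85)
  se_val <- c(1.18,
              NA, 0.61, 0.72, 0.65,
              NA, 0.69, 0.71,
              NA, 3956.18, 2315.47, 0.93, 1.34, 0.50, 3956.18, 3956.18, 1835.12, 1.47,
              0.65, 0.90, 0.41, 0.48, 1.46,
              NA, 0.78, 0.48,
              NA, 0.61, 0.62)
  predictor <- c("intercept",
                 rep("neuter_status", 4),
                 rep("age", 3),
                 rep("breed", 10),
                 SIGN_FIELDS,
                 rep("usg", 3),
                 rep("alp", 3))
  category <- c("(intercept)",
                NEUTER_LEVELS,
                AGE3_LEVELS,
                MODEL_BREEDS,
                rep("yes", 5),
                USG_LEVELS,
                ALP_LEVELS)
  out <- data.frame(predictor = predictor, category = category,
                    estimate = if (set == "development") est_dev else est_val,
                    se = if (set == "development") se_dev else se_val,
                    stringsAsFactors = FALSE)
  structure(out, class = c("cushing_coefficients", "data.frame"), set = set)
}

#' Final diagnoses recorded for the non-cases
#'
#' Counts of non-cases (n = 150) per final-diagnosis disease category, as
#' recorded in the medical records of the external-validation cohort.
#' Non-cases without a final diagnosis fall in the `"no_final_diagnosis"`
#' category (n = 25), so 125 of 150 non-cases had a final diagnosis.
#'
#' @return data frame with columns `category` and `n`.
#' @export
noncase_final_diagnoses <- function() {
  data.frame(
    category = c("cardiorespiratory", "dermatological", "endocrine",
                 "gastrointestinal", "hepatobiliary", "miscellaneous",
                 "neoplastic", "neurological", "ocular", "orthopedic",
                 "renal", "urogenital", "no_final_diagnosis"),
    n = c(6L, 2L, 23L, 20L, 4L, 14L, 10L, 12L, 5L, 1L, 18L, 10L, 25L),
    stringsAsFactors = FALSE
  )
}

#' Contingency tables reported with the external validation
#'
#' The 2x2 (and one 2x4) contingency tables that can be reconstructed
#' exactly from the reported counts: clinical signs and comorbidities
#' stratified case vs non-case (comorbidity tables use the recorded-only
#' denominators, i.e. "not recorded" excluded), neuter status by outcome,
#' and the development-vs-validation cohort prevalence table.
#'
#' @return named list of integer matrices with informative dimnames.
#' @export
published_contingency_tables <- function() {
  tab <- function(m, rn, cn) {
    dimnames(m) <- list(rn, cn)
    m
  }
  cc <- c("case", "noncase")
  list(
    vomiting = tab(matrix(c(3L, 77L, 20L, 130L), 2, byrow = TRUE), cc, c("yes", "no")),
    diabetes_mellitus = tab(matrix(c(0L, 71L, 12L, 130L), 2, byrow = TRUE), cc, c("yes", "no")),
    gall_bladder_content = tab(matrix(c(10L, 60L, 6L, 122L), 2, byrow = TRUE), cc, c("abnormal", "normal")),
    lymphopenia = tab(matrix(c(13L, 26L, 14L, 76L), 2, byrow = TRUE), cc, c("decreased", "not_decreased")),
    hypercholesterolemia = tab(matrix(c(8L, 9L, 7L, 38L), 2, byrow = TRUE), cc, c("elevated", "not_elevated")),
    neuter_status = tab(matrix(c(9L, 29L, 22L, 20L, 17L, 78L, 16L, 39L), 2, byrow = TRUE),
                        cc, NEUTER_LEVELS),
    prevalence_dev_vs_val = tab(matrix(c(398L, 541L, 80L, 150L), 2, byrow = TRUE),
                                c("development", "validation"), cc)
  )
}
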