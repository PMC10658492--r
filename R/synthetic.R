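# Synthetic dog-cohort generator: independent predictor marginals, a true
# logistic outcome model, and controllable miscalibration (offset delta on
# the log-odds, slope multiplier gamma).

.check_marginal <- function(p, name) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop("marginal for ", name, " must be non-negative and sum to 1", call. = FALSE)
  }
  p
}

#' Specify a synthetic cohort
#'
#' Defines everything needed to simulate a dog-level cohort: the number of
#' dogs, per-category marginal probabilities for each predictor (sampled
#' independently - only marginals, not a joint distribution, are emulated),
#' the true coefficient set generating the outcome, a miscalibration offset
#' `delta` (log-odds added to every linear predictor) and slope multiplier
#' `gamma`, and the RNG seed. The outcome is Bernoulli with probability
#' `plogis(delta + gamma * lp)` where `lp` is the true model's linear
#' predictor.
#'
#' Ages are sampled uniformly within the drawn age band (bands `<7`,
#' `7_to_<11`, `>=11`; lower bound 2 years, upper cap 16 years).
#'
#' @param n number of dogs (>= 0).
#' @param neuter,age_band,breed,usg,alp named probability vectors over the
#'   canonical categories of each predictor (breed over the ten model
#'   categories, age over the three model bands).
#' @param signs named vector of presence probabilities for the five
#'   clinical signs.
#' @param coefficients true coefficient table, default the
#'   development-cohort coefficients.
#' @param delta miscalibration offset on the log-odds scale (default 0).
#' @param gamma slope multiplier (> 0, default 1).
#' @param seed integer RNG seed.
#' @return object of class `cushing_cohort_spec`.
#' @seealso [validation_casemix_spec()] for the packaged case-mix matching the
#'   external-validation cohort.
#' @export
cohort_spec <- function(n,
                        neuter = c(female_entire = 0.25, female_neutered = 0.25,
                                   male_entire = 0.25, male_neutered = 0.25),
                        age_band = c("<7" = 1/3, "7_to_<11" = 1/3, ">=11" = 1/3),
                        breed = setNames(rep(0.1, 10), MODEL_BREEDS),
                        signs = c(polydipsia = 0.5, vomiting = 0.1,
                                  potbelly_hepatomegaly = 0.5, alopecia = 0.3,
                                  pruritus = 0.05),
                        usg = c(dilute = 1/3, not_dilute = 1/3, not_recorded = 1/3),
                        alp = c(elevated = 1/3, not_elevated = 1/3, not_recorded = 1/3),
                        coefficients = cushing_coefficients("development"),
                        delta = 0, gamma = 1, seed = 1L) {
  stopifnot(n >= 0, gamma > 0, is.numeric(delta))
  stopifnot(setequal(names(neuter), NEUTER_LEVELS),
            setequal(names(age_band), AGE3_LEVELS),
            setequal(names(breed), MODEL_BREEDS),
            setequal(names(signs), SIGN_FIELDS),
            setequal(names(usg), USG_LEVELS),
            setequal(names(alp), ALP_LEVELS))
  .check_marginal(neuter, "neuter_status")
  .check_marginal(age_band, "age_band")
  .check_marginal(breed, "breed")
  .check_marginal(usg, "usg")
  .check_marginal(alp, "alp")
  if (any(signs < 0 | signs > 1)) stop("sign probabilities must be in [0, 1]", call. = FALSE)
  structure(list(n = as.integer(n), neuter = neuter, age_band = age_band,
                 breed = breed, signs = signs, usg = usg, alp = alp,
                 coefficients = coefficients, delta = delta, gamma = gamma,
                 seed = as.integer(seed)),
            class = "cushing_cohort_spec")
}

#' Generate a synthetic cohort
#'
#' Draws predictors independently from the spec's marginals and the outcome
#' from the true logistic model with the spec's miscalibration. Fully
#' reproducible from the spec's seed: the same spec always yields the
#' identical cohort.
#'
#' @param spec a [cohort_spec()].
#' @return cohort data frame with columns `id`, the ten predictors,
#'   `true_probability` (the generating Bernoulli probability) and
#'   `outcome` (1 = case).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cushing_cohort_spec"))
  n <- spec$n
  if (n == 0) {
    out <- data.frame(id = integer(), neuter_status = character(),
                      age_years = numeric(), breed = character(),
                      polydipsia = logical(), vomiting = logical(),
                      potbelly_hepatomegaly = logical(), alopecia = logical(),
                      pruritus = logical(), usg = character(), alp = character(),
                      true_probability = numeric(), outcome = integer(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  set.seed(spec$seed)
  draw <- function(p) sample(names(p), n, replace = TRUE, prob = p)
  band <- draw(spec$age_band)
  lo <- c("<7" = 2, "7_to_<11" = 7, ">=11" = 11)[band]
  hi <- c("<7" = 7, "7_to_<11" = 11, ">=11" = 16)[band]
  age <- runif(n, lo, hi)
  out <- data.frame(
    id = seq_len(n),
    neuter_status = draw(spec$neuter),
    age_years = age,
    breed = draw(spec$breed),
    stringsAsFactors = FALSE
  )
  for (sign in SIGN_FIELDS) {
    out[[sign]] <- runif(n) < spec$signs[[sign]]
  }
  out$usg <- draw(spec$usg)
  out$alp <- draw(spec$alp)
  lp <- linear_predictor(out, spec$coefficients)
  out$true_probability <- plogis(spec$delta + spec$gamma * lp)
  out$outcome <- rbinom(n, 1L, out$true_probability)
  out
}

#' Cohort spec matching the external-validation case mix
#'
#' A packaged [cohort_spec()] whose predictor marginals match the reported
#' external-validation cohort frequencies (neuter status 11.3/46.5/16.5/
#' 25.7%; age bands 13.9/43.0/43.0%; polydipsia 86.5%, vomiting 10.0%,
#' potbelly/hepatomegaly 52.6%, alopecia 30.9%, pruritus 4.8%; USG
#' 39.6/10.9/49.6%; ALP 56.5/31.7/11.7%; breed frequencies per the
#' development-vs-validation comparison) and whose true coefficients are
#' the development-cohort set. Marginals printed to 1 decimal are
#' renormalised to sum exactly to 1.
#'
#' @param n cohort size, default 230 (the validation cohort's size).
#' @param delta,gamma miscalibration controls, defaults 0 and 1.
#' @param seed integer RNG seed.
#' @return a `cushing_cohort_spec`.
#' @export
validation_casemix_spec <- function(n = 230, delta = 0, gamma = 1, seed = 1L) {
  norm <- function(p) p / sum(p)
  cohort_spec(
    n = n,
    neuter = norm(c(female_entire = 11.3, female_neutered = 46.5,
                    male_entire = 16.5, male_neutered = 25.7)),
    age_band = norm(c("<7" = 13.9, "7_to_<11" = 43.0, ">=11" = 43.0)),
    breed = norm(c(crossbreed = 19.1, bichon_frise = 0.4, border_terrier = 0.9,
                   jack_russell_terrier = 6.5, labrador_retriever = 2.6,
                   other_purebred = 66.1, schnauzer = 0.4,
                   staffordshire_bull_terrier = 0.4,
                   west_highland_white_terrier = 1.3, yorkshire_terrier = 2.2)),
    signs = c(polydipsia = 0.865, vomiting = 0.100,
              potbelly_hepatomegaly = 0.526, alopecia = 0.309, pruritus = 0.048),
    usg = norm(c(dilute = 39.6, not_dilute = 10.9, not_recorded = 49.6)),
    alp = norm(c(elevated = 56.5, not_elevated = 31.7, not_recorded = 11.7)),
    coefficients = cushing_coefficients("development"),
    delta = delta, gamma = gamma, seed = seed
  )
}
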