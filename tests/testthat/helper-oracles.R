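# Independent oracles used across the suite. These deliberately re-derive
# results through a different route than the package code.

# Literal transcription of the published points grid in long form, used as a
# lookup-and-sum scoring oracle independent of score_cohort()'s internals.
points_long <- data.frame(
  predictor = c(rep("neuter_status", 4), rep("age", 2), rep("breed", 6),
                rep("polydipsia", 2), rep("vomiting", 2),
                rep("potbelly_hepatomegaly", 2), rep("alopecia", 2),
                rep("pruritus", 2), rep("usg", 3), rep("alp", 3)),
  category = c("female_entire", "female_neutered", "male_entire", "male_neutered",
               "<7", ">=7",
               "bichon_frise", "border_terrier", "labrador_retriever",
               "schnauzer", "west_highland_white_terrier", "other",
               "yes", "no", "yes", "no", "yes", "no", "yes", "no", "yes", "no",
               "dilute", "not_dilute", "not_recorded",
               "elevated", "not_elevated", "not_recorded"),
  points = c(0, -1, -1, -1,
             0, 1,
             2, 1, -3, -2, -3, 0,
             2, 0, -2, 0, 3, 0, 2, 0, -2, 0,
             0, -2, -1,
             0, -3, 0),
  stringsAsFactors = FALSE
)

lookup_points <- function(predictor, category) {
  hit <- points_long$predictor == predictor & points_long$category == category
  stopifnot(sum(hit) == 1)
  points_long$points[hit]
}

# brute-force score for one cohort row, category by category
oracle_score <- function(row) {
  signs <- c("polydipsia", "vomiting", "potbelly_hepatomegaly", "alopecia", "pruritus")
  total <- lookup_points("neuter_status", row$neuter_status) +
    lookup_points("age", if (row$age_years < 7) "<7" else ">=7") +
    lookup_points("breed", normalise_breed(row$breed, "score"))
  for (s in signs) {
    total <- total + lookup_points(s, if (isTRUE(row[[s]])) "yes" else "no")
  }
  total + lookup_points("usg", row$usg) + lookup_points("alp", row$alp)
}

# random cohort of raw (un-normalised) profiles
random_profiles <- function(n, seed = 1) {
  set.seed(seed)
  breeds <- c("Bichon Frise", "border terrier", "Labrador Retriever",
              "schnauzer", "West Highland White Terrier", "beagle",
              "crossbreed", "Jack Russell terrier", "dachshund",
              "Staffordshire bull terrier", "yorkie", "poodle")
  data.frame(
    neuter_status = sample(c("female_entire", "female_neutered",
                             "male_entire", "male_neutered"), n, replace = TRUE),
    age_years = round(runif(n, 0, 16), 1),
    breed = sample(breeds, n, replace = TRUE),
    polydipsia = sample(c(TRUE, FALSE), n, replace = TRUE),
    vomiting = sample(c(TRUE, FALSE), n, replace = TRUE),
    potbelly_hepatomegaly = sample(c(TRUE, FALSE), n, replace = TRUE),
    alopecia = sample(c(TRUE, FALSE), n, replace = TRUE),
    pruritus = sample(c(TRUE, FALSE), n, replace = TRUE),
    usg = sample(c("dilute", "not_dilute", "not_recorded"), n, replace = TRUE),
    alp = sample(c("elevated", "not_elevated", "not_recorded"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# exhaustive pairwise c-statistic: concordant + half ties over all pairs
pair_count_c <- function(predicted, observed) {
  xs <- predicted[observed == 1]
  ys <- predicted[observed == 0]
  tot <- 0
  for (x in xs) for (y in ys) tot <- tot + (x > y) + 0.5 * (x == y)
  tot / (length(xs) * length(ys))
}

# independent Freeman-Halton oracle for 2 x c tables: enumerate the first row
# with expand.grid and sum probabilities computed from log-factorials
enum_fisher_2xc <- function(tab, tol = 1e-7) {
  stopifnot(nrow(tab) == 2)
  rm <- rowSums(tab); cm <- colSums(tab); N <- sum(tab)
  logp <- function(top) {
    bottom <- cm - top
    if (any(bottom < 0)) return(-Inf)
    sum(lfactorial(rm)) + sum(lfactorial(cm)) - lfactorial(N) -
      sum(lfactorial(c(top, bottom)))
  }
  grid <- expand.grid(lapply(cm, function(m) 0:m))
  grid <- grid[rowSums(grid) == rm[1], , drop = FALSE]
  lp <- apply(grid, 1, logp)
  lp_obs <- logp(tab[1, ])
  sum(exp(lp[lp <= lp_obs + log1p(tol)]))
}

# independent hypergeometric 2x2 oracle via log-factorials (no dhyper)
enum_fisher_2x2 <- function(tab, tol = 1e-7) {
  rm <- rowSums(tab); cm <- colSums(tab); N <- sum(tab)
  support <- max(0, cm[1] - rm[2]):min(cm[1], rm[1])
  logp <- function(a) {
    cells <- c(a, rm[1] - a, cm[1] - a, rm[2] - cm[1] + a)
    sum(lfactorial(rm)) + sum(lfactorial(cm)) - lfactorial(N) -
      sum(lfactorial(cells))
  }
  lp <- vapply(support, logp, numeric(1))
  lp_obs <- logp(tab[1, 1])
  sum(exp(lp[lp <= lp_obs + log1p(tol)]))
}
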