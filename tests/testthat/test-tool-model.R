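test_that("worked scoring examples reproduce the published grid", {
  baseline <- predictor_profile("female_entire", 5, "crossbreed",
                                usg = "dilute", alp = "elevated")
  expect_identical(score_cohort(baseline)$total, 0L)

  mixed <- predictor_profile("male_neutered", 9, "Labrador retriever",
                             polydipsia = TRUE, potbelly_hepatomegaly = TRUE,
                             usg = "not_recorded", alp = "not_recorded")
  sc <- score_cohort(mixed)
  expect_identical(sc$total, 1L)
  # per-predictor contributions are recorded and sum to the total
  expect_identical(sc$neuter_status, -1L)
  expect_identical(sc$breed, -3L)
  expect_identical(sc$usg, -1L)
  expect_equal(rowSums(sc[, setdiff(names(sc), "total")]), 1, ignore_attr = TRUE)

  top <- predictor_profile("female_entire", 8, "bichon frise",
                           polydipsia = TRUE, potbelly_hepatomegaly = TRUE,
                           alopecia = TRUE, usg = "dilute", alp = "elevated")
  expect_identical(score_cohort(top)$total, 10L)

  bottom <- predictor_profile("male_entire", 5, "West Highland White Terrier",
                              vomiting = TRUE, pruritus = TRUE,
                              usg = "not_dilute", alp = "not_elevated")
  expect_identical(score_cohort(bottom)$total, -13L)
})

test_that("unknown categories are rejected naming the field", {
  bad <- data.frame(neuter_status = "spayed", age_years = 5, breed = "beagle")
  expect_error(score_cohort(bad), "neuter_status")
  bad2 <- predictor_profile("female_entire", 5, "beagle")
  bad2$usg <- "cloudy"
  expect_error(score_cohort(bad2), "usg")
})

test_that("missing signs resolve to absent, missing labs to not_recorded", {
  minimal <- data.frame(neuter_status = "female_entire", age_years = 3,
                        breed = "crossbreed")
  sc <- score_cohort(minimal)
  # all signs absent contribute 0; usg not_recorded -1, alp not_recorded 0
  expect_identical(sc$total, -1L)
})

test_that("score range is found by exhaustive enumeration", {
  expect_identical(score_range(), c(-13L, 10L))
  zero <- cushing_points_grid()
  for (nm in names(zero)) zero[[nm]][] <- 0L
  expect_identical(score_range(zero), c(0L, 0L))
  labs_only <- cushing_points_grid()[c("usg", "alp")]
  expect_identical(score_range(labs_only), c(-5L, 0L))
})

test_that("scoring matches a brute-force lookup-and-sum oracle on random profiles", {
  profiles <- random_profiles(1000, seed = 11)
  got <- score_cohort(profiles)$total
  want <- vapply(seq_len(nrow(profiles)),
                 function(i) oracle_score(profiles[i, ]), numeric(1))
  expect_equal(got, as.integer(want))
  expect_true(all(got >= -13 & got <= 10))
})

test_that("linear predictor sums the published coefficients", {
  baseline <- predictor_profile("female_entire", 5, "crossbreed",
                                usg = "dilute", alp = "elevated")
  expect_equal(linear_predictor(baseline), -0.49)

  dog <- predictor_profile("female_neutered", 8, "crossbreed",
                           polydipsia = TRUE, potbelly_hepatomegaly = TRUE,
                           usg = "dilute", alp = "elevated")
  expect_equal(linear_predictor(dog), -0.49 - 0.64 + 0.64 + 0.87 + 1.11)

  zeroed <- cushing_coefficients("development")
  zeroed$estimate[] <- 0
  expect_equal(linear_predictor(dog, zeroed), 0)
})

test_that("predicted probabilities are the logistic transform of the linear predictor", {
  baseline <- predictor_profile("female_entire", 5, "crossbreed",
                                usg = "dilute", alp = "elevated")
  expect_equal(predict_probability(baseline), 0.3799, tolerance = 1e-4,
               ignore_attr = TRUE)
  dog <- predictor_profile("female_neutered", 8, "crossbreed",
                           polydipsia = TRUE, potbelly_hepatomegaly = TRUE,
                           usg = "dilute", alp = "elevated")
  expect_equal(predict_probability(dog), 0.8161, tolerance = 1e-4,
               ignore_attr = TRUE)
  zeroed <- cushing_coefficients("development")
  zeroed$estimate[] <- 0
  expect_equal(predict_probability(dog, zeroed), 0.5, ignore_attr = TRUE)
})

test_that("probability is monotone in each positive coefficient", {
  base <- predictor_profile("female_entire", 5, "crossbreed",
                            usg = "dilute", alp = "elevated")
  with_sign <- base
  for (s in c("polydipsia", "potbelly_hepatomegaly", "alopecia")) {
    with_sign <- base
    with_sign[[s]] <- TRUE
    expect_gt(predict_probability(with_sign), predict_probability(base))
  }
})

test_that("score and full-model linear predictor are positively rank-correlated", {
  profiles <- random_profiles(1000, seed = 23)
  sc <- score_cohort(profiles)$total
  lp <- linear_predictor(profiles)
  expect_gt(cor(sc, lp, method = "kendall"), 0)
})

test_that("score lookup maps, clips, and validates", {
  lookup <- data.frame(score = -13:10,
                       probability = seq(0, 0.96, length.out = 24))
  expect_equal(score_to_probability(10, lookup), 0.96, ignore_attr = TRUE)
  # published floor of 0% is clipped up to keep logits finite
  expect_equal(score_to_probability(-13, lookup), 0.001, ignore_attr = TRUE)
  flat <- data.frame(score = -13:10, probability = 0.5)
  expect_equal(score_to_probability(c(-5, 0, 7), flat), rep(0.5, 3),
               ignore_attr = TRUE)
  expect_error(score_to_probability(11, lookup), "range")
  bad <- lookup
  bad$probability[5] <- 0.9  # breaks monotonicity
  expect_error(score_to_probability(0, bad), "monotone")
})

test_that("breed normalisation distinguishes score and model baselines", {
  expect_identical(normalise_breed("Westie"), "west_highland_white_terrier")
  expect_identical(normalise_breed("BEAGLE!"), "other")
  expect_identical(normalise_breed("beagle", "model"), "other_purebred")
  expect_identical(normalise_breed("mixed breed", "model"), "crossbreed")
  expect_identical(normalise_breed("mixed breed", "score"), "other")
  expect_identical(normalise_breed("Jack Russell terrier", "model"),
                   "jack_russell_terrier")
  # the score grid has no Jack Russell category
  expect_identical(normalise_breed("Jack Russell terrier", "score"), "other")
})

test_that("age band edges are closed on the left", {
  p7 <- predictor_profile("female_entire", 7, "crossbreed",
                          usg = "dilute", alp = "elevated")
  expect_identical(score_cohort(p7)$age, 1L)            # 7 -> ">=7"
  expect_equal(linear_predictor(p7), -0.49 + 0.64)      # 7 -> "7_to_<11"
  p11 <- predictor_profile("female_entire", 11, "crossbreed",
                           usg = "dilute", alp = "elevated")
  expect_equal(linear_predictor(p11), -0.49 + 0.58)     # 11 -> ">=11"
})
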