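test_that("2x2 exact test reproduces reported sign and comorbidity associations", {
  expect_equal(fisher_exact_2x2(matrix(c(5, 5, 5, 5), 2)), 1)
  tabs <- published_contingency_tables()
  # expected values frozen from an independent implementation (stats::fisher.test)
  expect_equal(fisher_exact_2x2(tabs$vomiting), 0.02125409, tolerance = 1e-6)
  expect_equal(round(fisher_exact_2x2(tabs$vomiting), 2), 0.02)
  expect_equal(fisher_exact_2x2(tabs$diabetes_mellitus), 0.009549447,
               tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(tabs$gall_bladder_content), 0.02706993,
               tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(tabs$lymphopenia), 0.03304373, tolerance = 1e-6)
  expect_equal(fisher_exact_2x2(tabs$hypercholesterolemia), 0.01796559,
               tolerance = 1e-6)
  expect_equal(round(fisher_exact_2x2(tabs$hypercholesterolemia), 2), 0.02)
})

test_that("2x2 exact test validates its input", {
  expect_error(fisher_exact_2x2(matrix(c(1, 2, 3), 3, 1)), "2 rows")
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
  expect_error(fisher_exact_2x2(matrix(c(1.5, 2, 3, 4), 2)), "integers")
  expect_error(fisher_exact_2x2(matrix(1:6, 2, 3)), "rxc")
})

test_that("r x c exact test matches enumeration oracles and the 2x2 special case", {
  neuter <- published_contingency_tables()$neuter_status
  expect_equal(fisher_exact_rxc(neuter), 0.009587184, tolerance = 1e-6)
  expect_equal(round(fisher_exact_rxc(neuter), 2), 0.01)
  # proportional rows: independence holds exactly at the mode
  prop <- matrix(c(2, 4, 6, 1, 2, 3), 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(prop), 1)
  small <- matrix(c(2, 3, 1, 1, 2, 4), 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(small), enum_fisher_2xc(small), tolerance = 1e-10)
  # r x c reduces exactly to the 2x2 test on 2x2 input
  t22 <- matrix(c(3, 9, 8, 2), 2)
  expect_identical(fisher_exact_rxc(t22), fisher_exact_2x2(t22))
  # cross-check against an independent implementation on random tables
  set.seed(31)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 4) + 1, 2, 3)
    expect_equal(fisher_exact_rxc(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-6)
  }
})

test_that("r x c enumeration guard routes large tables to Monte Carlo", {
  big <- matrix(c(200, 150, 100, 120, 130, 110), 2, byrow = TRUE)
  expect_error(fisher_exact_rxc(big), "simulate")
  small <- matrix(c(2, 3, 1, 1, 2, 4), 2, byrow = TRUE)
  pmc <- fisher_exact_rxc(small, simulate = TRUE, B = 2e4, seed = 5)
  expect_lt(abs(pmc - enum_fisher_2xc(small)), 0.02)
  # seeded Monte Carlo is reproducible
  expect_identical(pmc, fisher_exact_rxc(small, simulate = TRUE, B = 2e4, seed = 5))
})

test_that("exact p-values lie in (0, 1] and are permutation-invariant", {
  set.seed(17)
  for (i in 1:30) {
    tab <- matrix(rpois(4, 6) + 1, 2)
    p <- fisher_exact_2x2(tab)
    expect_gt(p, 0)
    expect_lte(p, 1)
    expect_equal(fisher_exact_2x2(tab[2:1, ]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(tab[, 2:1]), p, tolerance = 1e-12)
    expect_equal(fisher_exact_2x2(t(tab)), p, tolerance = 1e-12)
  }
})

test_that("rank-sum comparison follows the exactness rules", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  # enumeration of the 6 rank assignments gives 2/6
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(10, 11)), 1 / 3, tolerance = 1e-12)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "non-empty")
})

test_that("rank-sum test holds its type-I error under the null", {
  set.seed(71)
  rejections <- 0L
  for (i in 1:200) {
    x <- rnorm(50); y <- rnorm(50)
    if (wilcoxon_rank_sum(x, y) < 0.05) rejections <- rejections + 1L
  }
  rate <- rejections / 200
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.11)
})

test_that("baseline table summarises strata and picks the right test", {
  # degenerate two-record cohort: percentages computed, test not meaningful
  toy <- data.frame(outcome = c(1, 0), polydipsia = c(TRUE, TRUE))
  tab <- suppressWarnings(baseline_table(toy, "polydipsia"))
  expect_match(tab$`0`[1], "100.0")
  expect_match(tab$`1`[1], "100.0")
  expect_true(is.na(tab$p[1]))

  # built-in association (odds ratio 3) is detected at n = 400
  set.seed(12)
  y <- rbinom(400, 1, 0.5)
  x <- rbinom(400, 1, plogis(qlogis(0.3) + log(3) * y))
  coh <- data.frame(outcome = y, flag = x == 1, noise = rnorm(400))
  tab <- baseline_table(coh, c("flag", "noise"))
  expect_lt(tab$p[tab$variable == "flag"][1], 0.05)
  expect_identical(tab$test[tab$variable == "noise"], "wilcoxon_rank_sum")
  expect_warning(baseline_table(coh, c("flag", "absent_column")), "skipped")
})

test_that("baseline table reconstructs the reported vomiting row exactly", {
  counts <- published_contingency_tables()$vomiting
  coh <- data.frame(
    outcome = rep(c(1, 0), times = rowSums(counts)),
    vomiting = c(rep(c(TRUE, FALSE), counts[1, ]),
                 rep(c(TRUE, FALSE), counts[2, ]))
  )
  tab <- baseline_table(coh, "vomiting")
  yes <- tab[tab$category == "yes", ]
  expect_match(yes$`1`, "^3 \\(3\\.8\\)")
  expect_match(yes$`0`, "^20 \\(13\\.3\\)")
  expect_equal(min(tab$p, na.rm = TRUE), 0.02125409, tolerance = 1e-6)
})

test_that("cohort comparison reconstructs counts from percentages", {
  a <- data.frame(variable = "outcome", category = "case", percent = 42.4)
  b <- data.frame(variable = "outcome", category = "case", percent = 34.8)
  cmp <- cohort_compare(a, b, n_a = 939, n_b = 230)
  expect_identical(cmp$count_a, 398L)
  expect_identical(cmp$count_b, 80L)
  expect_equal(round(cmp$p, 2), 0.04)
  expect_true(cmp$reconstructed)

  same <- data.frame(variable = "v", category = c("x", "y"), count = c(30, 70))
  cmp2 <- cohort_compare(same, same, n_a = 100, n_b = 100)
  expect_equal(cmp2$p, c(1, 1))
  expect_false(any(cmp2$reconstructed))

  # category missing from one summary yields a row with missing p
  extra <- rbind(same, data.frame(variable = "v", category = "z", count = 5))
  cmp3 <- cohort_compare(extra, same, n_a = 105, n_b = 100)
  expect_true(is.na(cmp3$p[cmp3$category == "z"]))
})

test_that("counts -> percentages -> counts round-trips at 1-decimal precision", {
  set.seed(41)
  for (i in 1:50) {
    total <- sample(50:1000, 1)
    count <- sample(0:total, 1)
    pct <- round(100 * count / total, 1)
    expect_identical(as.integer(round(pct * total / 100)), count)
  }
})
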