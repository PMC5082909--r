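test_that("one-in-N prevalence reproduces the cohort's printed values", {
  n <- ea_cohort_numbers()
  expect_equal(one_in_n_prevalence(n$total_cases, n$births), 17300L)
  expect_equal(one_in_n_prevalence(n$eligible_cases, n$births), 39700L)
  expect_equal(one_in_n_prevalence(1, 100), 100L)
  expect_error(one_in_n_prevalence(0, 100), "zero cases")
  expect_error(one_in_n_prevalence(10, 5), "births < cases")
})

test_that("the exclusion cascade audits each step and checks totals", {
  n <- ea_cohort_numbers()
  res <- exclusion_cascade(n$total_cases, n$exclusions)
  expect_equal(res$remaining, 51L)
  expect_equal(nrow(res$audit), 4L)
  expect_equal(res$audit$remaining[4], 51L)
  # identity with no exclusions
  expect_equal(exclusion_cascade(10, integer())$remaining, 10L)
  # overrun errors
  expect_error(exclusion_cascade(10, c(a = 8, b = 5)), "exceed")
})

test_that("Pearson chi-square matches the printed sex-table p-value", {
  res <- pearson_chi_square(c(1036825, 986210), c(30, 21))
  expect_equal(res$p_value, 0.28, tolerance = 0.01 / 0.28)
  expect_equal(res$df, 1)
  # identical proportions give statistic 0, p 1
  res2 <- pearson_chi_square(c(100, 100), c(10, 10))
  expect_equal(res2$statistic, 0)
  expect_equal(res2$p_value, 1)
  res3 <- pearson_chi_square(c(10, 10), c(10, 10))
  expect_equal(res3$statistic, 0)
  expect_error(pearson_chi_square(c(0, 0), c(1, 2)), "zero marginal")
  expect_error(pearson_chi_square(c(10), c(5)), "categories")
})

test_that("chi-square agrees with the closed-form 2x2 statistic", {
  # independent oracle: X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  closed_form <- function(a, b, c_, d) {
    a <- as.numeric(a); b <- as.numeric(b); c_ <- as.numeric(c_); d <- as.numeric(d)
    N <- a + b + c_ + d
    N * (a * d - b * c_)^2 / ((a + b) * (c_ + d) * (a + c_) * (b + d))
  }
  set.seed(19)
  for (rep in 1:50) {
    m <- matrix(sample(1:500, 4, replace = TRUE), 2)
    got <- suppressWarnings(pearson_chi_square(m[, 1], m[, 2]))
    expect_equal(got$statistic,
                 closed_form(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-10)
    expect_equal(got$p_value,
                 pchisq(got$statistic, df = 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("column percentages reproduce the demographics table", {
  t1 <- ea_table1()
  # case percentages: every printed cell matches at one decimal
  for (ch in unique(t1$characteristic)) {
    d <- t1[t1$characteristic == ch, ]
    expect_equal(percent_of_column(d$case_count), d$printed_case_pct,
                 info = paste("case", ch))
  }
  # population percentages match except two cells the source table printed
  # as residuals to 100 rather than from their own counts:
  # race "Other" (printed 1.6, counts give 1.5) and sex "Female"
  # (printed 48.8, counts give 48.7)
  residual_cells <- c("race_ethnicity.Other", "case_sex.Female")
  recomputed_residuals <- c(1.5, 48.7)
  for (ch in unique(t1$characteristic)) {
    d <- t1[t1$characteristic == ch, ]
    got <- percent_of_column(d$population_count)
    cellkey <- paste(ch, d$category, sep = ".")
    known <- cellkey %in% residual_cells
    expect_equal(got[!known], d$printed_population_pct[!known], info = ch)
    if (any(known)) {
      expect_equal(got[known],
                   recomputed_residuals[match(cellkey[known], residual_cells)])
      expect_equal(abs(got[known] - d$printed_population_pct[known]),
                   rep(0.1, sum(known)))
    }
  }
  expect_equal(percent_of_column(c(157085, 2022740 - 157085))[1], 7.8)
  expect_error(percent_of_column(c(0, 0)), "zero column total")
})

test_that("percentages over a partition sum to ~100", {
  set.seed(3)
  for (rep in 1:20) {
    counts <- sample(1:10000, sample(2:4, 1))
    expect_lte(abs(sum(percent_of_column(counts)) - 100), 0.2)
  }
})

test_that("the demographics report recomputes every characteristic's p-value", {
  t1 <- ea_table1()
  rep_ <- suppressWarnings(demographics_report(t1))
  # per-characteristic p-values at the table's printed precision
  printed <- unique(t1[, c("characteristic", "printed_p")])
  for (i in seq_len(nrow(printed))) {
    got <- unique(rep_$p_value[rep_$characteristic == printed$characteristic[i]])
    expect_equal(round(got, 2), printed$printed_p[i],
                 info = printed$characteristic[i])
  }
})
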