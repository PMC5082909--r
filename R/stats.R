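#' Birth prevalence as "1 in N"
#'
#' `births / cases`, rounded half away from zero to the nearest hundred — the
#' convention recovered from the study's printed prevalences.
#' @param cases number of cases (>= 1).
#' @param births number of live births.
#' @return integer N such that prevalence is 1 in N.
#' @export
one_in_n_prevalence <- function(cases, births) {
  if (cases < 1) stop("one_in_n_prevalence: zero cases", call. = FALSE)
  if (births < cases) stop("one_in_n_prevalence: births < cases", call. = FALSE)
  as.integer(round_half_away(births / cases / 100) * 100)
}

#' Case exclusion cascade with audit trail
#'
#' Subtracts labeled exclusion counts from a starting total, recording each
#' step; errors if the exclusions overrun the total.
#' @param total starting case count.
#' @param exclusions named integer vector of disjoint exclusion counts.
#' @return list with `remaining` and an `audit` tibble (step, excluded,
#'   remaining).
#' @export
exclusion_cascade <- function(total, exclusions) {
  remaining <- total
  steps <- list()
  for (nm in names(exclusions)) {
    remaining <- remaining - exclusions[[nm]]
    if (remaining < 0) {
      stop("exclusion_cascade: exclusions exceed total at step ", nm, call. = FALSE)
    }
    steps[[length(steps) + 1]] <- tibble::tibble(
      step = nm, excluded = as.integer(exclusions[[nm]]),
      remaining = as.integer(remaining)
    )
  }
  list(remaining = as.integer(remaining),
       audit = if (length(steps)) dplyr::bind_rows(steps) else
         tibble::tibble(step = character(), excluded = integer(), remaining = integer()))
}

#' Pearson chi-square homogeneity test
#'
#' Classical Pearson statistic on a categories x (population, cases) count
#' table, df = categories - 1, upper-tail p, no continuity correction — the
#' comparison used for the cohort demographics table.
#' @param population,cases integer count vectors over the same categories.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
pearson_chi_square <- function(population, cases) {
  if (length(population) != length(cases) || length(population) < 2) {
    stop("pearson_chi_square: need >= 2 matching categories", call. = FALSE)
  }
  m <- cbind(population, cases)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("pearson_chi_square: zero marginal", call. = FALSE)
  }
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Column percentages at one decimal
#'
#' `100 * count / total`, rounded half away from zero to one decimal, as
#' printed in the demographics table.
#' @param counts non-negative counts forming a column.
#' @return percentages (one decimal) summing to ~100.
#' @export
percent_of_column <- function(counts) {
  total <- sum(counts)
  if (total <= 0) stop("percent_of_column: zero column total", call. = FALSE)
  round_half_away(100 * counts / total, 1)
}

#' Demographics report mirroring the cohort comparison table
#'
#' Recomputes percentages and the Pearson chi-square p-value per
#' characteristic from a long demographics table.
#' @param demographics tibble with `characteristic`, `category`,
#'   `population_count`, `case_count`.
#' @return tibble adding `population_pct`, `case_pct` and per-characteristic
#'   `p_value`.
#' @export
demographics_report <- function(demographics) {
  out <- lapply(split(demographics, demographics$characteristic), function(d) {
    d$population_pct <- percent_of_column(d$population_count)
    d$case_pct <- percent_of_column(d$case_count)
    d$p_value <- pearson_chi_square(d$population_count, d$case_count)$p_value
    d
  })
  dplyr::bind_rows(out)
}
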