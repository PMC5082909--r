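fc_with_refs <- function(...) {
  filter_config(reference_sets = list(
    hapmap_cnp = make_ref("1", 1, 1),        # placeholder far from test calls
    chop_blocks = make_ref("1", 1, 1),
    internal_controls = make_ref("1", 1, 1),
    unrelated_case_db = make_ref("1", 1, 1)), ...)
}

test_that("overlap profiles match CNV type and union same-type features", {
  call <- make_call(start = 1e6, end = 1e6 + 99999, copy_number = 1L)
  call$cnv_type <- "loss"
  fc <- filter_config(reference_sets = list(
    hapmap_cnp = make_ref("1", 1e6, 2e6, "loss"),
    chop_blocks = make_ref("1", 1e6, 2e6, "gain"),
    internal_controls = make_ref("2", 1e6, 2e6, "loss"),
    unrelated_case_db = make_ref("1", 1e6, 2e6, "both")))
  p <- profile_overlaps(call, fc)
  expect_equal(unname(p["hapmap_cnp"]), 1.0)        # same type, full cover
  expect_equal(unname(p["chop_blocks"]), 0.0)       # opposite type ignored
  expect_equal(unname(p["internal_controls"]), 0.0) # wrong chromosome
  expect_equal(unname(p["unrelated_case_db"]), 1.0) # "both" matches either
  fc2 <- fc; fc2$reference_sets$dgv_extra <- NULL
  fc_bad <- fc; fc_bad$reference_sets <- list(hapmap_cnp = NULL)
  expect_error(profile_overlaps(call, fc_bad), "missing reference set")
})

test_that("autosomal selection applies the probe, size and overlap floors", {
  base <- function(...) {
    calls <- make_call(...)
    calls$cnv_type <- "loss"
    calls
  }
  fc <- fc_with_refs()
  # 9 probes, 30 Kb: probe floor
  r1 <- select_autosomal_candidates(
    base(start = 1e6, end = 1e6 + 29999, n_probes = 9L), fc, audit = TRUE)
  expect_equal(r1$fate, "filtered_probes")
  # 12 probes, 24.4 Kb: size floor
  r2 <- select_autosomal_candidates(
    base(start = 1e6, end = 1e6 + 24399, n_probes = 12L), fc, audit = TRUE)
  expect_equal(r2$fate, "filtered_size")
  # overlap boundary is strict: exactly 35% rejected, 34.9% retained
  call40 <- base(start = 1e6, end = 1e6 + 39999, n_probes = 15L)
  mkfc <- function(frac) {
    filter_config(reference_sets = list(
      hapmap_cnp = make_ref("1", 1e6, 1e6 + round(frac * 40000) - 1, "loss")))
  }
  at_boundary <- select_autosomal_candidates(call40, mkfc(0.35), audit = TRUE)
  expect_equal(at_boundary$fate, "filtered_common")
  below <- select_autosomal_candidates(call40, mkfc(0.349), audit = TRUE)
  expect_equal(below$fate, "retained")
  # sex-chromosome calls are not autosomal candidates
  xcall <- base(chrom = "X", start = 1e6, end = 2e6)
  expect_equal(nrow(select_autosomal_candidates(xcall, fc)), 0L)
})

test_that("selection filters are monotone in their thresholds", {
  set.seed(5)
  calls <- dplyr::bind_rows(lapply(1:30, function(i) {
    s <- sample.int(5e6, 1)
    k <- make_call(start = s, end = s + sample.int(1e5, 1) + 5e3,
                   n_probes = sample(5:30, 1), copy_number = sample(c(1L, 3L), 1))
    k
  }))
  calls$cnv_type <- ifelse(calls$copy_number < 2, "loss", "gain")
  refs <- list(hapmap_cnp = dplyr::bind_rows(lapply(1:5, function(i) {
    s <- sample.int(5e6, 1)
    make_ref("1", s, s + 8e4, sample(c("loss", "gain", "both"), 1))
  })))
  kept_ids <- function(max_ov, min_kb) {
    fc <- filter_config(max_ref_overlap = max_ov, min_size_kb = min_kb,
                        reference_sets = refs)
    out <- select_autosomal_candidates(calls, fc)
    paste(out$start, out$end)
  }
  expect_true(all(kept_ids(0.35, 25) %in% kept_ids(0.50, 25)))
  expect_true(all(kept_ids(0.35, 40) %in% kept_ids(0.35, 25)))
})

test_that("DGV exclusion needs multiple same-type entries each covering half", {
  cand <- make_call(start = 1e6, end = 1e6 + 99999)
  cand$cnv_type <- "loss"
  fc <- filter_config()
  two80 <- dplyr::bind_rows(make_ref("1", 1e6, 1e6 + 79999, "loss"),
                            make_ref("1", 1e6 + 20000, 1e6 + 99999, "loss"))
  expect_true(flag_dgv_exclusion(cand, two80, fc))
  one100 <- make_ref("1", 1e6, 1e6 + 99999, "loss")
  expect_false(flag_dgv_exclusion(cand, one100, fc))
  opp <- dplyr::bind_rows(make_ref("1", 1e6, 1e6 + 99999, "gain"),
                          make_ref("1", 1e6, 1e6 + 99999, "gain"))
  expect_false(flag_dgv_exclusion(cand, opp, fc))
})

test_that("sex-chromosome selection handles PAR/XTR diploidy and size", {
  sex <- c(s1 = "F", s2 = "M")
  par <- tibble::tibble(chrom = c("X", "Y"), start = c(1, 1), end = c(1e6, 1e6))
  xtr <- tibble::tibble(chrom = "X", start = 15e6, end = 15.5e6)
  calls <- dplyr::bind_rows(
    make_call(sample = "s1", chrom = "X", start = 2e6, end = 2e6 + 358999,
              copy_number = 3L),                       # 359 Kb female X dup
    make_call(sample = "s2", chrom = "X", start = 5e5, end = 5e5 + 49999,
              copy_number = 2L),                       # copy-2 inside PAR
    make_call(sample = "s1", chrom = "X", start = 8e6, end = 8e6 + 19999,
              copy_number = 1L))                       # 20 Kb, below floor
  calls <- assign_region_class(calls, par, xtr)
  fc <- fc_with_refs()
  out <- select_sex_chromosome_candidates(calls, fc, sex, audit = TRUE)
  expect_equal(out$fate, c("retained", "filtered_diploid_par", "filtered_size"))
  expect_equal(out$sex[1], "F")
  expect_error(select_sex_chromosome_candidates(calls, fc, c(s1 = "F")),
               "unknown sample sex")
})

test_that("recurrence groups same-type overlapping candidates across cases", {
  cands2 <- dplyr::bind_rows(
    make_call(sample = "A", chrom = "8", start = 1e6, end = 1.4e6, copy_number = 3L),
    make_call(sample = "B", chrom = "8", start = 1.1e6, end = 1.45e6, copy_number = 3L),
    make_call(sample = "C", chrom = "8", start = 1.1e6, end = 1.45e6, copy_number = 1L),
    make_call(sample = "D", chrom = "3", start = 5e6, end = 5.2e6, copy_number = 1L))
  cands2$cnv_type <- ifelse(cands2$copy_number < 2, "loss", "gain")
  out <- count_recurrence(cands2)
  expect_equal(out$cnv_id[1], out$cnv_id[2])       # same-type pair grouped
  expect_true(out$recurrent[1])
  expect_equal(out$n_cases_sharing[1], 2L)
  expect_false(out$cnv_id[3] == out$cnv_id[2])     # del vs dup never grouped
  expect_false(out$recurrent[4])
  expect_equal(out$n_cases_sharing[4], 1L)
  # partition: every candidate belongs to exactly one group
  expect_equal(length(out$cnv_id), nrow(cands2))
  expect_false(any(is.na(out$cnv_id)))
  # deterministic under permutation
  perm <- count_recurrence(cands2[c(3, 1, 4, 2), ])
  expect_equal(sort(table(perm$cnv_id)), sort(table(out$cnv_id)))
})

test_that("ranking export applies per-caller floors and PAR exclusions", {
  calls <- dplyr::bind_rows(
    make_call(caller = "pennstyle", n_probes = 9L, start = 1e6, end = 1e6 + 29999),
    make_call(caller = "pennstyle", n_probes = 10L, start = 1e6, end = 1e6 + 29999),
    make_call(caller = "partitionstyle", n_probes = 5L, start = 1e6, end = 1e6 + 25999),
    make_call(caller = "partitionstyle", n_probes = 5L, start = 1e6, end = 1e6 + 19999),
    make_call(caller = "partitionstyle", chrom = "X", start = 5e5,
              end = 5e5 + 29999, copy_number = 2L),
    make_call(caller = "partitionstyle", chrom = "X", start = 2e6,
              end = 2e6 + 29999, copy_number = 3L))
  calls <- assign_region_class(
    calls, tibble::tibble(chrom = "X", start = 1, end = 1e6), NULL)
  out <- export_ranking_input(calls)
  expect_equal(nrow(out), 3L)
  expect_false(any(out$n_probes == 9L & out$caller == "pennstyle"))
  expect_true(any(out$caller == "partitionstyle" & out$chrom == "1"))
  expect_false(any(out$copy_number == 2L & out$chrom == "X"))  # PAR copy-2 out
  expect_true(any(out$chrom == "X" & out$copy_number == 3L))
})

test_that("LRR review passes supported calls and flags flat intensity", {
  set.seed(9)
  probes <- tibble::tibble(
    sample = "s1", chrom = "1", position = seq(1e6, 1e6 + 5e4, by = 1000),
    lrr = rnorm(51, 0.3, 0.1))
  cand <- make_call(start = 1e6, end = 1e6 + 5e4, copy_number = 3L)
  cand$cnv_type <- "gain"
  expect_equal(review_flag_lrr(cand, probes), "pass")
  flat <- probes; flat$lrr <- rnorm(51, 0, 0.05)
  expect_equal(review_flag_lrr(cand, flat), "fail")
  wrong <- probes; wrong$lrr <- rnorm(51, -0.45, 0.1)
  expect_equal(review_flag_lrr(cand, wrong), "fail")   # wrong sign
})
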