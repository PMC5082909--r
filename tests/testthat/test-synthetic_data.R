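test_that("identical seeds give byte-identical bundles", {
  cfg <- small_cohort_config(seed = 21)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, d1)
  generate_cohort(cfg, d2)
  files <- sort(list.files(d1, recursive = TRUE))
  expect_equal(files, sort(list.files(d2, recursive = TRUE)))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE), info = f)
  }
  # a different seed changes the bundle
  d3 <- withr::local_tempdir()
  generate_cohort(small_cohort_config(seed = 22), d3)
  expect_false(identical(readLines(file.path(d1, "truth.tsv")),
                         readLines(file.path(d3, "truth.tsv"))))
})

test_that("planted events are in bounds with one well-formed fate each", {
  cfg <- small_cohort_config(seed = 33)
  b <- generate_cohort(cfg, withr::local_tempdir())
  ev <- b$events
  expect_true(all(ev$start >= 1))
  expect_true(all(ev$end <= cfg$chromosomes[ev$chrom]))
  expect_true(all(ev$end > ev$start))
  fates <- c("retained_candidate", "filtered_probes", "filtered_size",
             "filtered_common", "filtered_dgv", "artifact_flagged", "not_called")
  expect_true(all(ev$expected_fate %in% fates))
  expect_equal(anyDuplicated(ev$event_id), 0L)
  # class-fate consistency
  expect_true(all(ev$expected_fate[ev$class == "common_cnp"] %in%
                    c("filtered_common", "not_called")))
  expect_true(all(ev$expected_fate[ev$class == "dgv_like"] %in%
                    c("filtered_dgv", "not_called")))
  expect_true(all(ev$expected_fate[ev$class == "artifact"] %in%
                    c("artifact_flagged", "not_called")))
  # recurrent pairs sit at identical coordinates in two samples
  rec <- ev[!is.na(ev$recurrent_group), ]
  for (g in unique(rec$recurrent_group)) {
    pair <- rec[rec$recurrent_group == g, ]
    expect_equal(nrow(pair), 2L)
    expect_equal(length(unique(pair$sample)), 2L)
    expect_equal(length(unique(pair$start)), 1L)
  }
  # common events are present in both common reference sets
  common <- ev[ev$class == "common_cnp", ]
  for (i in seq_len(nrow(common))) {
    hit <- b$reference_sets$hapmap_cnp$start == common$start[i] &
      b$reference_sets$hapmap_cnp$end == common$end[i]
    expect_true(any(hit))
  }
})

test_that("the bundle is read back exactly by the io layer", {
  cfg <- small_cohort_config(seed = 44)
  d <- withr::local_tempdir()
  b <- generate_cohort(cfg, d)
  # caller files parse to the emitted calls
  penn_files <- list.files(file.path(d, "calls"), "penn", full.names = TRUE)
  penn <- dplyr::bind_rows(lapply(penn_files, read_cnv_calls, dialect = "pennstyle"))
  emitted_penn <- b$calls[b$calls$caller == "pennstyle", ]
  expect_equal(nrow(penn), nrow(emitted_penn))
  expect_setequal(paste(penn$sample, penn$chrom, penn$start, penn$end),
                  paste(emitted_penn$sample, emitted_penn$chrom,
                        emitted_penn$start, emitted_penn$end))
  part_files <- list.files(file.path(d, "calls"), "partition", full.names = TRUE)
  part <- dplyr::bind_rows(lapply(part_files, read_cnv_calls, dialect = "partitionstyle"))
  expect_equal(nrow(part), sum(b$calls$caller == "partitionstyle"))
  # reference sets and GMT round-trip
  refs <- read_reference_cnv_set(file.path(d, "hapmap_cnp.tsv"))
  expect_equal(nrow(refs), nrow(b$reference_sets$hapmap_cnp))
  lib <- read_gene_set_library(file.path(d, "gene_sets.gmt"))
  expect_equal(length(lib), length(b$gene_sets))
  expect_setequal(lib$planted_enriched, toupper(b$gene_sets$planted_enriched))
  # probe table sorted and complete
  probes <- read_probe_table(file.path(d, "probes.tsv"))
  expect_equal(nrow(probes), nrow(b$probes))
  expect_false(is.unsorted(probes$position[probes$sample == probes$sample[1] &
                                             probes$chrom == "1"]))
})

test_that("planted variant read counts behave like their binomial models", {
  cfg <- cohort_config(seed = 55, n_true_het = 400, n_artifact_variants = 400,
                       n_common_variants = 0, n_noimpact_variants = 0)
  set.seed(cfg$seed)
  vg <- generate_variants(cfg)
  truth <- vg$truth
  ab <- truth$alt_reads / (truth$ref_reads + truth$alt_reads)
  het <- truth$class == "true_het"
  expect_gte(mean(ab[het] >= 0.4 & ab[het] <= 0.85), 0.95)
  expect_gte(mean(ab[!het] < 0.25), 0.95)
  expect_true(all(truth$ref_reads + truth$alt_reads >= cfg$depth_min))
  # empty configuration gives an empty table
  cfg0 <- cohort_config(seed = 1, n_true_het = 0, n_artifact_variants = 0,
                        n_common_variants = 0, n_noimpact_variants = 0)
  set.seed(1)
  expect_equal(nrow(generate_variants(cfg0)$variants), 0L)
})

test_that("a cohort with no planted events yields no candidates", {
  cfg <- small_cohort_config(seed = 66, n_events = 0, n_recurrent_pairs = 0,
                             n_roh = 0)
  d <- withr::local_tempdir()
  b <- generate_cohort(cfg, d)
  res <- suppressWarnings(run_pipeline(pipeline_config_from_bundle(d)))
  expect_equal(nrow(res$candidates), 0L)
  # false-positive caller noise exists but is all sub-threshold
  expect_gt(nrow(res$audit), 0L)
  expect_true(all(res$audit$fate %in% c("filtered_probes", "filtered_size",
                                        "filtered_common")))
})
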