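test_that("caller confidence and probe thresholds match the calling setup", {
  calls <- dplyr::bind_rows(
    make_call(caller = "partitionstyle", confidence = 34.9),
    make_call(caller = "partitionstyle", confidence = 35.0),
    make_call(caller = "pennstyle", confidence = 10.0),
    make_call(caller = "pennstyle", confidence = 9.99),
    make_call(caller = "pennstyle", confidence = 50, n_probes = 2L))
  kept <- apply_caller_thresholds(calls)
  expect_equal(nrow(kept), 2L)
  expect_equal(kept$confidence, c(35.0, 10.0))
  # idempotent
  expect_equal(apply_caller_thresholds(kept), kept)
})

test_that("adjacent same-state calls merge by the gap-fraction rule", {
  two <- dplyr::bind_rows(
    make_call(start = 1000, end = 10000, n_probes = 10L, confidence = 30),
    make_call(start = 11000, end = 20000, n_probes = 8L, confidence = 20))
  merged <- merge_adjacent_calls(two)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$start, 1000)
  expect_equal(merged$end, 20000)
  expect_equal(merged$n_probes, 18L)       # probe counts sum
  expect_equal(merged$confidence, 20)      # confidence is the minimum
  # different copy numbers never merge
  mixed <- two
  mixed$copy_number <- c(1L, 3L)
  expect_equal(nrow(merge_adjacent_calls(mixed)), 2L)
  # a single call and a fixed point are unchanged
  expect_equal(merge_adjacent_calls(two[1, ]), two[1, ])
  expect_equal(merge_adjacent_calls(merged), merged)
  expect_error(merge_adjacent_calls(two, gap_fraction = -0.1), "negative")
})

test_that("merging iterates to a fixed point and never loses covered bases", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(3:8, 1)
    s <- sort(sample.int(1e6, n))
    calls <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
      make_call(start = s[i], end = s[i] + sample.int(5e4, 1), n_probes = 5L)
    }))
    merged <- merge_adjacent_calls(calls)
    expect_equal(merge_adjacent_calls(merged), merged)   # idempotent
    covered <- function(x) {
      sum(IRanges::width(IRanges::reduce(IRanges::IRanges(x$start, x$end))))
    }
    expect_gte(covered(merged), covered(calls))
    expect_equal(sum(merged$n_probes), sum(calls$n_probes))
  }
})

test_that("concordance labels require 50% reciprocal overlap and type match", {
  penn <- make_call(caller = "pennstyle", start = 1e6, end = 1e6 + 9999,
                    copy_number = 1L)
  # identical call in both lists
  part_same <- make_call(caller = "partitionstyle", start = 1e6,
                         end = 1e6 + 9999, copy_number = 1L)
  lab <- label_concordance(penn, part_same)
  expect_equal(sort(unique(lab$concordance)), "both")
  # absent from the partition list
  lab2 <- label_concordance(penn, part_same[0, ])
  expect_equal(lab2$concordance, "penn_only")
  # 30% reciprocal overlap is below the rule
  part_small <- make_call(caller = "partitionstyle", start = 1e6,
                          end = 1e6 + 2999, copy_number = 1L)
  lab3 <- label_concordance(penn, part_small)
  expect_equal(lab3$concordance[lab3$caller == "pennstyle"], "penn_only")
  expect_equal(lab3$concordance[lab3$caller == "partitionstyle"], "partition_only")
  # opposite types never match
  part_gain <- make_call(caller = "partitionstyle", start = 1e6,
                         end = 1e6 + 9999, copy_number = 3L)
  lab4 <- label_concordance(penn, part_gain)
  expect_false(any(lab4$concordance == "both"))
})

test_that("concordance labeling is symmetric in the two callers", {
  set.seed(13)
  penn <- dplyr::bind_rows(lapply(1:6, function(i) {
    s <- sample.int(5e6, 1)
    make_call(caller = "pennstyle", start = s, end = s + sample.int(2e5, 1),
              copy_number = sample(c(1L, 3L), 1))
  }))
  part <- dplyr::bind_rows(lapply(1:6, function(i) {
    s <- sample.int(5e6, 1)
    make_call(caller = "partitionstyle", start = s, end = s + sample.int(2e5, 1),
              copy_number = sample(c(1L, 3L), 1))
  }))
  ab <- label_concordance(penn, part)
  # swap caller labels and the input order: "both" set must be preserved
  penn2 <- part; penn2$caller <- "pennstyle"
  part2 <- penn; part2$caller <- "partitionstyle"
  ba <- label_concordance(penn2, part2)
  key <- function(x) paste(x$sample, x$chrom, x$start, x$end, x$copy_number)
  both_ab <- sort(key(ab[ab$concordance == "both", ]))
  both_ba <- sort(key(ba[ba$concordance == "both", ]))
  expect_equal(both_ab, both_ba)
})

test_that("ROH detection needs 1 Mb span, a probe floor, and no heterozygote", {
  mkprobes <- function(n, spacing, genos, chrom = "1") {
    tibble::tibble(chrom = chrom, position = seq(1, by = spacing, length.out = n),
                   genotype = genos)
  }
  # 60 homozygous probes spanning ~1.2 Mb
  p <- mkprobes(60, 20e3, rep(c("AA", "BB"), 30))
  seg <- detect_roh(p, "s1")
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_probes, 60L)
  expect_gte(seg$end - seg$start + 1, 1e6)
  # same probes squeezed into 0.9 Mb: below the length rule
  p2 <- mkprobes(60, 15e3, rep("AA", 60))
  expect_equal(nrow(detect_roh(p2, "s1")), 0L)
  # one AB in the middle splits a 1.5 Mb run into two sub-Mb fragments
  genos <- rep("AA", 75); genos[38] <- "AB"
  p3 <- mkprobes(75, 20e3, genos)
  expect_equal(nrow(detect_roh(p3, "s1")), 0L)
  # no-calls are tolerated inside a run
  genos4 <- rep("AA", 60); genos4[c(10, 30)] <- "NC"
  p4 <- mkprobes(62, 20e3, c(genos4, "AB", "AB"))
  expect_equal(nrow(detect_roh(p4, "s1")), 1L)
  # unsorted input errors
  p5 <- p[c(2, 1, 3:60), ]
  expect_error(detect_roh(p5, "s1"), "sorted")
})
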