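#!/usr/bin/env Rscript
# Score the pipeline against the planted truth of the simulated cohort: did
# every planted event end up with the fate its class dictates (retained /
# filtered with the right reason / flagged as an intensity artifact)?

suppressMessages({library(eacnv); library(dplyr)})

truth <- utils::read.delim("results/cohort/truth.tsv",
                           colClasses = c(chrom = "character"))
audit <- utils::read.delim("results/cnv/audited_calls.tsv",
                           colClasses = c(chrom = "character"))
candidates <- read_candidate_report("results/cnv/candidates.tsv")

ev <- evaluate_truth_recovery(tibble::as_tibble(truth),
                              tibble::as_tibble(audit), candidates)
utils::write.table(as.data.frame(ev), "results/truth_recovery.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

scored <- ev[ev$expected_fate != "not_called", ]
cat("Planted-truth recovery (results/truth_recovery.tsv)\n")
cat(sprintf("  events scored: %d of %d (rest suppressed by caller noise)\n",
            nrow(scored), nrow(ev)))
by_fate <- scored %>%
  group_by(expected_fate) %>%
  summarize(n = dplyr::n(), correct = sum(fate_match), .groups = "drop")
print(as.data.frame(by_fate))
rare <- ev[ev$class == "rare_candidate" & ev$size_bp >= 25e3, ]
cat(sprintf("  filter-eligible rare events retained: %.1f%% (n = %d)\n",
            100 * mean(!is.na(rare$pipeline_fate) &
                         rare$pipeline_fate == "retained_candidate"),
            nrow(rare)))
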