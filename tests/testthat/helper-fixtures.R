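# Shared fixture builders for the test suite.

make_call <- function(sample = "s1", chrom = "1", start = 1e6, end = 2e6,
                      copy_number = 1L, n_probes = 20L, confidence = 50,
                      caller = "pennstyle", ...) {
  tibble::tibble(sample = sample, chrom = chrom, start = start, end = end,
                 copy_number = as.integer(copy_number),
                 n_probes = as.integer(n_probes), confidence = confidence,
                 caller = caller, start_marker = NA_character_,
                 end_marker = NA_character_, ...)
}

make_ref <- function(chrom = "1", start = 1e6, end = 2e6, type = "loss") {
  tibble::tibble(chrom = chrom, start = start, end = end, type = type)
}

# Per-base brute-force oracles for interval arithmetic (coordinates <= 1000).
brute_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end), seq(b$start, b$end)))
}

brute_coverage_fraction <- function(query, features) {
  marks <- rep(FALSE, query$end - query$start + 1)
  base_at <- seq(query$start, query$end)
  for (i in seq_len(nrow(features))) {
    if (features$chrom[i] != query$chrom) next
    marks <- marks | (base_at >= features$start[i] & base_at <= features$end[i])
  }
  mean(marks)
}

random_interval <- function(chrom = "1", max_coord = 1000) {
  s <- sample.int(max_coord, 1)
  e <- min(max_coord, s + sample.int(50, 1) - 1)
  tibble::tibble(chrom = chrom, start = s, end = e)
}

# Exhaustive hypergeometric tail: P[overlap >= k] by direct enumeration.
enum_hyper_tail <- function(N, K, n, k) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Manual BH step-up reference.
manual_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Reduced synthetic cohort used by several test files.
small_cohort_config <- function(seed = 11, n_events = 20, n_recurrent_pairs = 1, ...) {
  cohort_config(seed = seed, n_cases = 6, n_controls = 2, n_events = n_events,
                include_sex_chromosomes = FALSE,
                n_recurrent_pairs = n_recurrent_pairs, ...)
}
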